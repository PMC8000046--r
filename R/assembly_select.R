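#' Contig N50
#'
#' The largest contig length L such that contigs of length >= L together
#' cover at least half of the total assembly length.
#'
#' @param contig_lengths Nonempty numeric vector of positive contig
#'   lengths (bp).
#' @return The N50 length (same units as input).
#' @examples
#' n50(c(50, 40, 30, 20, 10))  # 40
#' @export
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("empty contig length list", call. = FALSE)
  if (any(is.na(contig_lengths)) || any(contig_lengths <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  lens <- sort(contig_lengths, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Select one representative assembly per species
#'
#' Among the candidate assemblies of each species, the one maximizing
#' sequencing coverage times contig N50 is selected as the species
#' representative. Exact product ties break first to the higher coverage,
#' then to the lexicographically smaller accession, so selection is
#' deterministic and invariant to input order.
#'
#' @param assemblies Assembly metadata from [read_assembly_metadata()]
#'   (columns `species_taxid`, `accession`, `coverage`, `n50`).
#' @return List with `selected` (data frame: one row per species with the
#'   winning accession and its selection score) and `scores` (the full
#'   audit table with every candidate's `coverage * n50` product).
#' @export
select_representative <- function(assemblies) {
  stopifnot(is.data.frame(assemblies), nrow(assemblies) > 0L)
  scores <- data.frame(species_taxid = assemblies$species_taxid,
                       accession = assemblies$accession,
                       coverage = assemblies$coverage,
                       n50 = assemblies$n50,
                       score = assemblies$coverage * assemblies$n50,
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$species_taxid, -scores$score,
                         -scores$coverage, scores$accession), , drop = FALSE]
  selected <- scores[!duplicated(scores$species_taxid), , drop = FALSE]
  rownames(scores) <- rownames(selected) <- NULL
  list(selected = selected, scores = scores)
}
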