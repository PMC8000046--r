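#' Rank genomes by a score
#'
#' Competition ("1224") ranking: scores sorted descending, tied scores
#' share the minimum rank and are flagged, and species name is the
#' secondary sort key so output order is deterministic without imposing an
#' order on ties.
#'
#' @param profiles Profile table from [score_genomes()].
#' @param metadata Genome metadata from [read_genome_metadata()]; every
#'   profiled genome must be present.
#' @param metric One of [SUBSTRATES], `"total"`, or a character vector of
#'   several substrates (ranked by their association sum).
#' @param mode `"redundant"` (degradation capacity) or `"unique"`
#'   (function specificity diversity).
#' @return Data frame with columns `rank`, `ordinal` (1..n positional
#'   rank), `genome_id`, `species`, `genus`, `class`, `phylum`, `score`,
#'   `tie` (logical).
#' @export
rank_genomes <- function(profiles, metadata,
                         metric = "total",
                         mode = c("redundant", "unique")) {
  mode <- match.arg(mode)
  if (nrow(profiles) == 0L) stop("no profiles to rank", call. = FALSE)
  missing <- setdiff(profiles$genome_id, metadata$genome_id)
  if (length(missing)) {
    stop("no metadata for genome_id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  score <- ranking_metric(profiles, metric, mode)
  md <- metadata[match(profiles$genome_id, metadata$genome_id), , drop = FALSE]
  ord <- order(-score, md$species, profiles$genome_id)
  score <- score[ord]
  md <- md[ord, , drop = FALSE]
  rk <- rank_competition(score)
  data.frame(rank = rk,
             ordinal = seq_along(score),
             genome_id = profiles$genome_id[ord],
             species = md$species, genus = md$genus,
             class = md$class, phylum = md$phylum,
             score = score,
             tie = duplicated(score) | duplicated(score, fromLast = TRUE),
             stringsAsFactors = FALSE)
}

ranking_metric <- function(profiles, metric, mode) {
  prefix <- if (mode == "redundant") "r_" else "u_"
  if (identical(metric, "total")) {
    return(if (mode == "redundant") profiles$total_redundant else profiles$total_unique)
  }
  unknown <- setdiff(metric, SUBSTRATES)
  if (length(unknown)) {
    stop("unknown ranking metric token '", unknown[1], "'", call. = FALSE)
  }
  cols <- paste0(prefix, metric)
  rowSums(as.matrix(profiles[, cols, drop = FALSE]))
}

# Minimum ("competition") rank for a descending-sorted score vector.
rank_competition <- function(sorted_scores) {
  n <- length(sorted_scores)
  if (n == 0L) return(integer(0))
  first <- match(sorted_scores, sorted_scores)  # first position of each value
  as.integer(first)
}

#' Phylum distribution over rank windows
#'
#' Counts species per phylum inside inclusive windows of ranking positions
#' (the 1-based ordinal position in the deterministically ordered ranking,
#' so tied competition ranks cannot straddle a window boundary ambiguously).
#'
#' @param ranking Ranking from [rank_genomes()].
#' @param windows List of inclusive `c(from, to)` position intervals;
#'   defaults to 1-500, 501-1000, 1001-end (trimmed to the ranking length).
#' @return Data frame: `window`, `from`, `to`, `phylum`, `count`.
#' @export
phylum_distribution <- function(ranking, windows = NULL) {
  n <- nrow(ranking)
  if (is.null(windows)) {
    edges <- unique(pmin(c(0, 500, 1000, n), n))
    windows <- Map(function(a, b) c(a + 1, b), edges[-length(edges)], edges[-1])
  }
  windows <- lapply(windows, as.integer)
  for (w in windows) {
    if (length(w) != 2L || w[1] < 1L || w[2] < w[1] || w[2] > n) {
      stop("invalid rank window [", paste(w, collapse = ", "),
           "] for a ranking of length ", n, call. = FALSE)
    }
  }
  covered <- unlist(lapply(windows, function(w) seq(w[1], w[2])))
  if (anyDuplicated(covered)) stop("overlapping rank windows", call. = FALSE)
  out <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    ph <- ranking$phylum[ranking$ordinal >= w[1] & ranking$ordinal <= w[2]]
    counts <- table(ph)
    data.frame(window = i, from = w[1], to = w[2],
               phylum = names(counts), count = as.integer(counts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intra-genus rank variation
#'
#' Summarizes, for every genus with enough ranked genomes, how widely its
#' species spread across the ranking.
#'
#' @param ranking Ranking from [rank_genomes()].
#' @param min_genomes Minimum genomes per genus to report (>= 2).
#' @return Data frame: `genus`, `n_genomes`, `best_rank`, `worst_rank`,
#'   `median_rank`, `spread` (worst - best), ordered by best rank.
#' @export
genus_variation <- function(ranking, min_genomes = 2L) {
  stopifnot(min_genomes >= 2L)
  split_ranks <- split(ranking$rank, ranking$genus)
  split_ranks <- split_ranks[lengths(split_ranks) >= min_genomes]
  out <- data.frame(
    genus = names(split_ranks),
    n_genomes = lengths(split_ranks),
    best_rank = vapply(split_ranks, min, numeric(1)),
    worst_rank = vapply(split_ranks, max, numeric(1)),
    median_rank = vapply(split_ranks, stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$spread <- out$worst_rank - out$best_rank
  out <- out[order(out$best_rank, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
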