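#' Read a per-protein CAZyme annotation table
#'
#' Reads a tab-separated annotation table (one row per protein annotation)
#' into validated annotation records. The dialect is declared, not guessed:
#' column names and the multi-EC delimiter default to common annotator
#' output but can be remapped for other dialects. Lines starting with `#`
#' are skipped and unknown extra columns are ignored.
#'
#' Family labels may carry subfamily / CUPP-group suffixes (`"GH5_7"`,
#' `"GH7:2.1"`); they are split into parent family and subfamily here. Rows
#' whose family fails the `(GH|GT|PL|CE|AA|CBM)<n>` pattern are rejected
#' with row-numbered diagnostics. An empty EC cell yields an empty
#' `ec_labels` entry (the record then produces no observation).
#'
#' @param path Path to the TSV file (UTF-8, with header).
#' @param columns Named list mapping the required roles `genome_id`,
#'   `protein_id`, `family`, `ec` (and the optional role `subfamily`) to
#'   column names in the file.
#' @param ec_delim Delimiter separating multiple EC labels in one cell.
#' @return Data frame with columns `genome_id`, `protein_id`, `family`
#'   (parent), `subfamily` (`NA` if absent) and the list-column `ec_labels`,
#'   in file order.
#' @export
read_annotations <- function(path,
                             columns = list(genome_id = "genome_id",
                                            protein_id = "protein_id",
                                            family = "family",
                                            subfamily = "subfamily",
                                            ec = "ec"),
                             ec_delim = ";") {
  tab <- read_tsv_checked(path, required = unlist(columns[c("genome_id", "protein_id", "family", "ec")]))
  if (nrow(tab) == 0L) {
    warning("annotation table '", path, "' contains no data rows", call. = FALSE)
    empty <- data.frame(genome_id = character(0), protein_id = character(0),
                        family = character(0), subfamily = character(0),
                        stringsAsFactors = FALSE)
    empty$ec_labels <- list()
    return(empty)
  }
  gid <- as.character(tab[[columns$genome_id]])
  pid <- as.character(tab[[columns$protein_id]])
  if (any(!nzchar(gid)) || any(!nzchar(pid))) {
    bad <- which(!nzchar(gid) | !nzchar(pid))[1]
    stop("row ", bad, ": empty genome_id or protein_id", call. = FALSE)
  }
  fam <- parse_family(as.character(tab[[columns$family]]))
  if (anyNA(fam$family)) {
    bad <- which(is.na(fam$family))
    stop("invalid CAZy family label(s): ",
         paste0("row ", bad, " ('", tab[[columns$family]][bad], "')", collapse = ", "),
         call. = FALSE)
  }
  sub_col <- columns$subfamily
  subfam <- fam$subfamily
  if (!is.null(sub_col) && sub_col %in% names(tab)) {
    explicit <- as.character(tab[[sub_col]])
    use <- !is.na(explicit) & nzchar(explicit)
    subfam[use] <- explicit[use]
  }
  ec_raw <- as.character(tab[[columns$ec]])
  ec_raw[is.na(ec_raw)] <- ""
  ec_labels <- lapply(strsplit(ec_raw, ec_delim, fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  out <- data.frame(genome_id = gid, protein_id = pid,
                    family = fam$family, subfamily = subfam,
                    stringsAsFactors = FALSE)
  out$ec_labels <- ec_labels
  out
}

#' Read a genome metadata table
#'
#' @param path TSV with columns `genome_id`, `species`, `genus`, `class`,
#'   `phylum`, `accession`.
#' @param extra_phyla Additional phylum names accepted beyond the built-in
#'   fungal list.
#' @return Data frame of genome metadata, one row per genome.
#' @export
read_genome_metadata <- function(path, extra_phyla = character(0)) {
  known <- c("Ascomycota", "Basidiomycota", "Chytridiomycota", "Mucoromycota",
             "Zoopagomycota", "Blastocladiomycota", "Cryptomycota",
             "Microsporidia", extra_phyla)
  tab <- read_tsv_checked(path, required = c("genome_id", "species", "genus",
                                             "class", "phylum", "accession"))
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicate genome_id in metadata: '",
         tab$genome_id[anyDuplicated(tab$genome_id)], "'", call. = FALSE)
  }
  unknown <- setdiff(unique(tab$phylum), known)
  if (length(unknown)) {
    stop("unknown phylum value(s): ", paste0("'", unknown, "'", collapse = ", "),
         "; extend via extra_phyla", call. = FALSE)
  }
  tab
}

#' Read a substrate-association map
#'
#' The map assigns observation-key patterns to target plant cell wall
#' substrates. Each row holds an EC pattern (exact canonical EC or `*`), a
#' family pattern (exact family or `*`) and a comma-separated nonempty
#' subset of `cellulose, xylan, pectin, lignin`.
#'
#' @param path TSV with columns `ec_pattern`, `family_pattern`, `substrates`.
#' @return A `substrate_map`: data frame with character columns
#'   `ec_pattern`, `family_pattern` and the list-column `substrates`.
#' @export
read_substrate_map <- function(path) {
  tab <- read_tsv_checked(path, required = c("ec_pattern", "family_pattern", "substrates"))
  if (nrow(tab) == 0L) stop("substrate map '", path, "' is empty", call. = FALSE)
  ec <- as.character(tab$ec_pattern)
  not_wild <- ec != "*"
  ec[not_wild] <- normalize_ec(ec[not_wild])
  fam <- as.character(tab$family_pattern)
  bad_fam <- fam != "*" & !grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$", fam)
  if (any(bad_fam)) {
    stop("invalid family pattern '", fam[which(bad_fam)[1]], "'", call. = FALSE)
  }
  key <- paste(ec, fam, sep = ";")
  if (anyDuplicated(key)) {
    stop("duplicate substrate-map entry for pattern '",
         key[anyDuplicated(key)], "'", call. = FALSE)
  }
  subs <- strsplit(as.character(tab$substrates), ",", fixed = TRUE)
  subs <- lapply(subs, function(x) trimws(x))
  for (i in seq_along(subs)) {
    unknown <- setdiff(subs[[i]], SUBSTRATES)
    if (length(unknown)) {
      stop("unknown substrate token '", unknown[1], "' in map row ", i, call. = FALSE)
    }
    if (length(subs[[i]]) == 0L) stop("empty substrate set in map row ", i, call. = FALSE)
  }
  out <- data.frame(ec_pattern = ec, family_pattern = fam, stringsAsFactors = FALSE)
  out$substrates <- subs
  class(out) <- c("substrate_map", class(out))
  out
}

#' The substrate map shipped with the package
#'
#' An illustrative curation of canonical cellulase, xylanase, pectin-active
#' and ligninolytic EC functions across their usual GH/PL/CE/AA families.
#' It is a working default for demonstration and testing, not a
#' comprehensive curation of all CAZyme substrate associations; supply your
#' own map for production analyses.
#'
#' @return A `substrate_map` (see [read_substrate_map()]).
#' @export
default_substrate_map <- function() {
  read_substrate_map(system.file("extdata", "substrate_map.tsv",
                                 package = "cazyrank", mustWork = TRUE))
}

#' Read assembly metadata for representative selection
#'
#' Every returned row has resolvable contig lengths or a precomputed N50:
#' a row may carry `n50` directly, a comma-separated `contig_lengths` cell,
#' or neither — in which case a contig FASTA named by accession must exist
#' under `fasta_dir` (extensions `.fasta`, `.fa`, `.fna`).
#'
#' @param path TSV with columns `species_taxid`, `accession`, `coverage`
#'   and optionally `n50` and/or `contig_lengths`.
#' @param fasta_dir Optional directory of contig FASTA files.
#' @return Data frame with columns `species_taxid`, `accession`, `coverage`,
#'   `n50` and list-column `contig_lengths` (`NULL` entries where only a
#'   precomputed N50 is available).
#' @export
read_assembly_metadata <- function(path, fasta_dir = NULL) {
  tab <- read_tsv_checked(path, required = c("species_taxid", "accession", "coverage"))
  n <- nrow(tab)
  cov <- suppressWarnings(as.numeric(tab$coverage))
  if (any(is.na(cov))) {
    warning("missing sequencing coverage treated as 0 for accession(s): ",
            paste(tab$accession[is.na(cov)], collapse = ", "), call. = FALSE)
    cov[is.na(cov)] <- 0
  }
  if (any(cov < 0)) stop("negative sequencing coverage", call. = FALSE)
  n50_col <- if ("n50" %in% names(tab)) suppressWarnings(as.numeric(tab$n50)) else rep(NA_real_, n)
  len_col <- if ("contig_lengths" %in% names(tab)) as.character(tab$contig_lengths) else rep(NA_character_, n)
  lengths_list <- vector("list", n)
  n50_out <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(n50_col[i])) {
      if (n50_col[i] <= 0) stop("non-positive n50 for accession '", tab$accession[i], "'", call. = FALSE)
      n50_out[i] <- n50_col[i]
      lengths_list[i] <- list(NULL)
    } else if (!is.na(len_col[i]) && nzchar(len_col[i])) {
      lens <- as.numeric(trimws(strsplit(len_col[i], ",", fixed = TRUE)[[1]]))
      lengths_list[[i]] <- lens
      n50_out[i] <- n50(lens)
    } else {
      lens <- contig_lengths_from_fasta(tab$accession[i], fasta_dir)
      lengths_list[[i]] <- lens
      n50_out[i] <- n50(lens)
    }
  }
  out <- data.frame(species_taxid = as.character(tab$species_taxid),
                    accession = as.character(tab$accession),
                    coverage = cov, n50 = n50_out, stringsAsFactors = FALSE)
  out$contig_lengths <- lengths_list
  out
}

contig_lengths_from_fasta <- function(accession, fasta_dir) {
  if (is.null(fasta_dir)) {
    stop("assembly '", accession,
         "' has neither n50 nor contig_lengths and no fasta_dir was given",
         call. = FALSE)
  }
  candidates <- file.path(fasta_dir, paste0(accession, c(".fasta", ".fa", ".fna")))
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0L) {
    stop("no contig FASTA found for accession '", accession, "' under ",
         fasta_dir, call. = FALSE)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    as.numeric(Biostrings::fasta.seqlengths(hit[1]))
  } else {
    lines <- readLines(hit[1])
    idx <- cumsum(startsWith(lines, ">"))
    body <- !startsWith(lines, ">")
    as.numeric(tapply(nchar(lines[body]), idx[body], sum))
  }
}

# Shared TSV reader: UTF-8, '#' comment lines skipped, tolerant of extra
# columns, fatal when a required column is absent.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write / read a genome profile table
#'
#' Profiles are serialized as TSV with full decimal precision so that a
#' write/read round trip reproduces scores bit-exactly.
#'
#' @param profiles Profile data frame from [score_genomes()].
#' @param path Output/input TSV path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns the profile data frame.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  tab$genome_id <- as.character(tab$genome_id)
  num <- setdiff(names(tab), "genome_id")
  tab[num] <- lapply(tab[num], as.numeric)
  tab
}

#' Convert a raw annotation table to annotation records
#'
#' Takes an in-memory data frame with columns `genome_id`, `protein_id`,
#' `family` and `ec` (one EC label per row, or delimiter-joined) and
#' produces the validated record format [read_annotations()] returns.
#'
#' @param df Raw annotation data frame.
#' @param ec_delim Delimiter for multi-EC cells.
#' @return Annotation records with parent `family`, `subfamily` and the
#'   `ec_labels` list-column.
#' @export
as_annotation_records <- function(df, ec_delim = ";") {
  fam <- parse_family(as.character(df$family))
  if (anyNA(fam$family)) {
    bad <- which(is.na(fam$family))[1]
    stop("invalid CAZy family label in row ", bad, ": '", df$family[bad], "'",
         call. = FALSE)
  }
  ec_raw <- as.character(df$ec)
  ec_raw[is.na(ec_raw)] <- ""
  out <- data.frame(genome_id = as.character(df$genome_id),
                    protein_id = as.character(df$protein_id),
                    family = fam$family, subfamily = fam$subfamily,
                    stringsAsFactors = FALSE)
  out$ec_labels <- lapply(strsplit(ec_raw, ec_delim, fixed = TRUE),
                          function(x) x[nzchar(trimws(x))])
  out
}
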