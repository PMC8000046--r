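#' Default substrate-association combinations
#'
#' The three combinations reported alongside single-substrate rankings:
#' cellulose + xylan, cellulose + xylan + lignin, and pectin + lignin.
#'
#' @return Named list of character vectors.
#' @export
default_combos <- function() {
  list(cellulose_xylan = c("cellulose", "xylan"),
       cellulose_xylan_lignin = c("cellulose", "xylan", "lignin"),
       pectin_lignin = c("pectin", "lignin"))
}

#' Run the full scoring and ranking pipeline
#'
#' Executes extract -> substrate map -> score -> rank -> RMS ->
#' association -> phylum distribution over an annotation table and writes
#' the report bundle: a full-precision profile table, capacity and
#' diversity rankings for the total, every substrate and every
#' association combination, the RMS table with `*` (high) / `¤` (low)
#' flags, the phylum distribution, and a JSON summary echoing the
#' configuration. Two runs with identical inputs produce byte-identical
#' outputs.
#'
#' @param annotations Path to the annotation TSV, or an annotation data
#'   frame from [read_annotations()].
#' @param metadata Path to the genome metadata TSV, or its data frame.
#' @param substrate_map Path to a substrate-map TSV, a `substrate_map`
#'   object, or `NULL` for the shipped default map.
#' @param out_dir Output directory for the report bundle.
#' @param excluded_families Families excluded from observation extraction.
#' @param combos Named list of substrate combinations to rank.
#' @param windows Rank windows for the phylum distribution (`NULL` for the
#'   defaults of [phylum_distribution()]).
#' @param top_n Number of rows in the JSON summary's hotspot lists.
#' @return Invisibly, a list with the computed `profiles`, `rankings`,
#'   `rms`, `phyla` and the written file paths.
#' @export
run_pipeline <- function(annotations, metadata, substrate_map = NULL,
                         out_dir = ".",
                         excluded_families = default_excluded_families(),
                         combos = default_combos(),
                         windows = NULL, top_n = 10L) {
  records <- if (is.character(annotations)) read_annotations(annotations) else annotations
  meta <- if (is.character(metadata)) read_genome_metadata(metadata) else metadata
  map <- if (is.null(substrate_map)) {
    default_substrate_map()
  } else if (is.character(substrate_map)) {
    read_substrate_map(substrate_map)
  } else {
    substrate_map
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  instances <- extract_observations(records, excluded_families)
  profiles <- score_genomes(instances, map)
  paths <- c(profiles = file.path(out_dir, "profiles.tsv"))
  write_profiles(profiles, paths[["profiles"]])

  rankings <- list()
  phyla <- NULL
  if (nrow(profiles) > 0L) {
    metrics <- c(list(total = "total"),
                 stats::setNames(as.list(SUBSTRATES), SUBSTRATES), combos)
    for (mode in c("redundant", "unique")) {
      for (mn in names(metrics)) {
        rk <- rank_genomes(profiles, meta, metric = metrics[[mn]], mode = mode)
        nm <- paste0(mode, "_", mn)
        rankings[[nm]] <- rk
        p <- file.path(out_dir, paste0("ranking_", nm, ".tsv"))
        paths[[paste0("ranking_", nm)]] <- p
        write_ranking(rk, profiles, p)
      }
    }
    phyla <- phylum_distribution(rankings$redundant_total, windows)
    paths[["phylum_distribution"]] <- file.path(out_dir, "phylum_distribution.tsv")
    utils::write.table(phyla, paths[["phylum_distribution"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    warning("no scored genomes: writing an all-zero report", call. = FALSE)
  }

  rms_tab <- rms_table(profiles)
  paths[["rms"]] <- file.path(out_dir, "rms.tsv")
  write_rms(rms_tab, paths[["rms"]])

  summary <- list(
    version = as.character(utils::packageVersion("cazyrank")),
    config = list(excluded_families = excluded_families,
                  combos = combos, top_n = top_n),
    n_genomes = nrow(profiles),
    n_instances = nrow(instances),
    total_redundant = sum(profiles$total_redundant),
    total_unique = sum(profiles$total_unique),
    top_capacity = if (nrow(profiles)) utils::head(
      rankings$redundant_total[, c("rank", "genome_id", "species", "score")],
      top_n) else NULL,
    top_diversity = if (nrow(profiles)) utils::head(
      rankings$unique_total[, c("rank", "genome_id", "species", "score")],
      top_n) else NULL
  )
  paths[["summary"]] <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(list(profiles = profiles, instances = instances,
                 rankings = rankings, rms = rms_tab, phyla = phyla,
                 paths = paths))
}

# Ranking TSV mirrors the hotspot table layout: rank, species, taxonomy,
# the four substrate scores of the ranking's mode, total, and the ranking
# score itself, with scores printed at one decimal (".0" dropped). The
# ordinal column preserves the deterministic row order next to the
# tie-aware competition rank.
write_ranking <- function(ranking, profiles, path) {
  idx <- match(ranking$genome_id, profiles$genome_id)
  mode_prefix <- if (grepl("unique", basename(path))) "u_" else "r_"
  tab <- data.frame(rank = ranking$rank, ordinal = ranking$ordinal,
                    genome_id = ranking$genome_id,
                    species = ranking$species, class = ranking$class,
                    phylum = ranking$phylum, stringsAsFactors = FALSE)
  for (s in SUBSTRATES) {
    tab[[s]] <- format_score(profiles[[paste0(mode_prefix, s)]][idx])
  }
  tot <- if (mode_prefix == "r_") profiles$total_redundant else profiles$total_unique
  tab$total <- format_score(tot[idx])
  tab$score <- format_score(ranking$score)
  tab$tie <- ifelse(ranking$tie, "*", "")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_rms <- function(rms_tab, path) {
  out <- data.frame(genome_id = rms_tab$genome_id, metric = rms_tab$metric,
                    redundant = format_score(rms_tab$redundant),
                    unique = format_score(rms_tab$unique),
                    rms = ifelse(is.na(rms_tab$ratio), "NA",
                                 sprintf("%.1f", rms_tab$ratio_rounded)),
                    flag = c(none = "", high = "*", low = "¤")[rms_tab$flag],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
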