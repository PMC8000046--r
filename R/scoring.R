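#' Score one genome's observation instances
#'
#' Computes, per substrate, the redundant score R_s (every protein-level
#' observation instance counted, measuring degradation capacity) and the
#' unique score U_s (every distinct observation key counted once, measuring
#' enzyme function specificity diversity), both under the half-count
#' substrate weighting. Instances whose key is not in the substrate map
#' contribute to neither mode.
#'
#' @param instances Observation instances for a single genome (see
#'   [extract_observations()]).
#' @param map A `substrate_map`.
#' @return A `genome_profile` list with elements `genome_id`, `redundant`
#'   and `unique` (named numeric vectors over [SUBSTRATES]),
#'   `total_redundant` and `total_unique`.
#' @export
score_genome <- function(instances, map) {
  stopifnot(is.data.frame(instances))
  gids <- unique(instances$genome_id)
  if (length(gids) > 1L) {
    stop("score_genome() received instances from multiple genomes: ",
         paste(gids, collapse = ", "), call. = FALSE)
  }
  red <- stats::setNames(numeric(length(SUBSTRATES)), SUBSTRATES)
  uni <- red
  if (nrow(instances) > 0L) {
    w <- substrate_weight_matrix(instances$key, map)
    red <- colSums(w)
    uw <- w[!duplicated(instances$key), , drop = FALSE]
    uni <- colSums(uw)
  }
  structure(list(genome_id = if (length(gids)) gids else NA_character_,
                 redundant = red, unique = uni,
                 total_redundant = sum(red), total_unique = sum(uni)),
            class = "genome_profile")
}

#' Score a cohort of genomes into a profile table
#'
#' @param instances Observation instances for one or more genomes.
#' @param map A `substrate_map`.
#' @return Data frame with one row per genome: `genome_id`, redundant
#'   scores `r_cellulose`..`r_lignin`, `total_redundant`, unique scores
#'   `u_cellulose`..`u_lignin`, `total_unique`. Genomes appear in first
#'   observation order.
#' @export
score_genomes <- function(instances, map) {
  gids <- unique(instances$genome_id)
  rows <- lapply(gids, function(g) {
    p <- score_genome(instances[instances$genome_id == g, , drop = FALSE], map)
    as.data.frame(c(list(genome_id = g),
                    as.list(stats::setNames(p$redundant, paste0("r_", SUBSTRATES))),
                    list(total_redundant = p$total_redundant),
                    as.list(stats::setNames(p$unique, paste0("u_", SUBSTRATES))),
                    list(total_unique = p$total_unique)),
                  stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    cols <- c("genome_id", paste0("r_", SUBSTRATES), "total_redundant",
              paste0("u_", SUBSTRATES), "total_unique")
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$genome_id <- character(0)
    return(out[, cols])
  }
  do.call(rbind, rows)
}

#' Total degradation capacity of a profile
#'
#' The sum of the four per-substrate redundant scores (the "Total" column
#' of a capacity ranking).
#'
#' @param profile A `genome_profile` or one row of a [score_genomes()]
#'   table.
#' @return Numeric total.
#' @export
total_capacity <- function(profile) {
  if (inherits(profile, "genome_profile")) return(sum(profile$redundant))
  sum(as.numeric(profile[paste0("r_", SUBSTRATES)]))
}

#' Substrate-association sum
#'
#' Sum of a profile's scores over a combination of substrates (e.g.
#' pectin + lignin), in either counting mode.
#'
#' @param profile A `genome_profile` or one row of a profile table.
#' @param combo Character subset of [SUBSTRATES].
#' @param mode `"redundant"` (capacity) or `"unique"` (diversity).
#' @return Numeric association sum.
#' @export
association_sum <- function(profile, combo, mode = c("redundant", "unique")) {
  mode <- match.arg(mode)
  unknown <- setdiff(combo, SUBSTRATES)
  if (length(unknown)) {
    stop("unknown substrate token '", unknown[1], "' in combination", call. = FALSE)
  }
  if (inherits(profile, "genome_profile")) {
    return(sum(profile[[mode]][combo]))
  }
  prefix <- if (mode == "redundant") "r_" else "u_"
  sum(as.numeric(profile[paste0(prefix, combo)]))
}

#' Redundancy Multiplication Score
#'
#' The ratio of a redundant score to the matching unique score: the factor
#' by which gene-copy redundancy multiplies an organism's degradation
#' capacity beyond its function specificity diversity. The reported ratio
#' is rounded half-up to one decimal; flags are assigned from the
#' *unrounded* ratio: `"high"` above 8, `"low"` below 3, `"none"`
#' otherwise. A zero unique score makes the ratio undefined (`NA`, flag
#' `"none"`), never zero or infinity.
#'
#' @param redundant,unique_ Non-negative scores (vectorized).
#' @return Data frame with columns `redundant`, `unique`, `ratio`
#'   (unrounded), `ratio_rounded` and `flag`.
#' @examples
#' rms(208, 16)  # ratio 13.0, flag "high"
#' rms(108, 22)  # ratio 4.9, flag "none"
#' @export
rms <- function(redundant, unique_) {
  stopifnot(length(redundant) == length(unique_))
  if (any(redundant < 0) || any(unique_ < 0)) {
    stop("RMS scores must be non-negative", call. = FALSE)
  }
  ratio <- ifelse(unique_ > 0, redundant / unique_, NA_real_)
  flag <- rep("none", length(ratio))
  flag[!is.na(ratio) & ratio > 8] <- "high"
  flag[!is.na(ratio) & ratio < 3] <- "low"
  data.frame(redundant = redundant, unique = unique_,
             ratio = ratio, ratio_rounded = round_half_up(ratio, 1),
             flag = flag, stringsAsFactors = FALSE)
}

#' RMS table for a profile table
#'
#' Computes the Redundancy Multiplication Score per substrate and for the
#' totals for every genome of a profile table.
#'
#' @param profiles Profile table from [score_genomes()].
#' @return Long data frame: `genome_id`, `metric` (substrate or
#'   `"total"`), `redundant`, `unique`, `ratio`, `ratio_rounded`, `flag`.
#' @export
rms_table <- function(profiles) {
  metrics <- c(SUBSTRATES, "total")
  out <- lapply(metrics, function(m) {
    if (m == "total") {
      r <- profiles$total_redundant; u <- profiles$total_unique
    } else {
      r <- profiles[[paste0("r_", m)]]; u <- profiles[[paste0("u_", m)]]
    }
    cbind(data.frame(genome_id = profiles$genome_id,
                     metric = rep(m, length(r)),
                     stringsAsFactors = FALSE),
          rms(r, u))
  })
  do.call(rbind, out)
}

# Round half away from zero at `digits` decimals (so 4.85 -> 4.9 at 1
# digit), unlike base round()'s round-half-even. Scores are non-negative
# so this is round-half-up.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Render a score the way the report tables print it: at most one decimal,
# trailing ".0" dropped.
format_score <- function(x) {
  r <- round_half_up(x, 1)
  out <- sprintf("%.1f", r)
  out <- sub("\\.0$", "", out)
  out[is.na(x)] <- "NA"
  out
}
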