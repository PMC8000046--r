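#' Resolve an observation key to weighted substrates
#'
#' Finds the most specific substrate-map entry matching the key's (EC,
#' family) pair and distributes unit weight evenly over the entry's
#' substrates. An EC associated with two substrates therefore counts as one
#' half for each (the half-count rule); the generalization to k substrates
#' is weight 1/k, which preserves the conservation the half-count rule
#' implies: the weights of any mapped key sum to exactly 1.
#'
#' Specificity order: exact EC + exact family beats exact EC + wildcard
#' family, which beats wildcard EC + exact family, which beats the
#' catch-all wildcard/wildcard. Two distinct entries can never match at the
#' same specificity tier (patterns match exactly and duplicates are
#' rejected on read), but the ambiguity check is kept defensively. An
#' unmapped key returns an empty weight vector.
#'
#' @param key Observation key string `"EC;FAMILY"`.
#' @param map A `substrate_map` from [read_substrate_map()].
#' @return Named numeric vector of substrate weights (empty when unmapped).
#' @examples
#' \dontrun{
#' substrates_for("3.2.1.4;GH5", default_substrate_map())
#' }
#' @export
substrates_for <- function(key, map) {
  stopifnot(inherits(map, "substrate_map"), length(key) == 1L)
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed observation key: '", key, "'", call. = FALSE)
  ec <- parts[1]; fam <- parts[2]
  ec_match <- map$ec_pattern == ec
  fam_match <- map$family_pattern == fam
  ec_wild <- map$ec_pattern == "*"
  fam_wild <- map$family_pattern == "*"
  # tier 1 = most specific
  tiers <- list(ec_match & fam_match,
                ec_match & fam_wild,
                ec_wild & fam_match,
                ec_wild & fam_wild)
  for (hit in tiers) {
    idx <- which(hit)
    if (length(idx) > 1L) {
      stop("ambiguous substrate map: entries ",
           paste0("(", map$ec_pattern[idx], ";", map$family_pattern[idx], ")",
                  collapse = " and "),
           " match key '", key, "' at equal specificity", call. = FALSE)
    }
    if (length(idx) == 1L) {
      subs <- map$substrates[[idx]]
      w <- rep(1 / length(subs), length(subs))
      names(w) <- subs
      return(w)
    }
  }
  stats::setNames(numeric(0), character(0))
}

# Vectorized resolution used by the scorer: one weight row per key over the
# canonical substrate order. Distinct keys are resolved once and recycled.
substrate_weight_matrix <- function(keys, map) {
  uk <- unique(keys)
  w <- matrix(0, nrow = length(uk), ncol = length(SUBSTRATES),
              dimnames = list(uk, SUBSTRATES))
  for (k in uk) {
    ws <- substrates_for(k, map)
    if (length(ws)) w[k, names(ws)] <- ws
  }
  w[keys, , drop = FALSE]
}
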