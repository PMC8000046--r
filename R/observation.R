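#' EC label normalization
#'
#' Parses and canonicalizes an Enzyme Commission label. The first three
#' fields must be positive integers; the fourth may be an integer or the
#' placeholder `*` (a `-` fourth field, the dialect some annotators emit for
#' an incomplete assignment, is rewritten to `*`). Full EC numbers pass
#' through unchanged.
#'
#' @param raw Character vector of raw EC labels, e.g. `"3.2.1.4"` or
#'   `"3.2.1.-"`.
#' @return Character vector of canonical EC labels, e.g. `"3.2.1.*"`.
#' @examples
#' normalize_ec("3.2.1.4")   # "3.2.1.4"
#' normalize_ec("3.2.1.-")   # "3.2.1.*"
#' @export
normalize_ec <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  stopifnot(is.character(raw))
  parts <- strsplit(raw, ".", fixed = TRUE)
  vapply(seq_along(raw), function(i) {
    p <- parts[[i]]
    if (length(p) != 4L ||
        !all(grepl("^[0-9]+$", p[1:3])) ||
        !grepl("^([0-9]+|\\*|-)$", p[4]) ||
        any(p[1:3] == "0")) {
      stop("invalid EC label: '", raw[i], "'", call. = FALSE)
    }
    if (p[4] == "-") p[4] <- "*"
    paste(p, collapse = ".")
  }, character(1))
}

#' Family label parsing
#'
#' Splits a raw CAZy family label into its parent family and an optional
#' subfamily/CUPP-group suffix. `"GH5_7"` and `"GH7:2.1"` both collapse to
#' parent `"GH5"` / `"GH7"`; a bare family passes through. Invalid labels
#' return `NA` for the family, allowing callers to report the offending row.
#'
#' @param raw Character vector of family labels.
#' @return Data frame with columns `family` and `subfamily` (`NA` when the
#'   label carries none; `family` is `NA` when the label is invalid).
#' @export
parse_family <- function(raw) {
  m <- regmatches(raw, regexec("^((GH|GT|PL|CE|AA|CBM)[0-9]+)([_:][0-9A-Za-z_.:]+)?$", raw))
  fam <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, character(1))
  sub <- vapply(m, function(x) {
    if (length(x) && nzchar(x[4])) x[1] else NA_character_
  }, character(1))
  data.frame(family = fam, subfamily = sub, stringsAsFactors = FALSE)
}

#' Construct a Function;Family observation key
#'
#' The integrated observation key combines a predicted EC function with the
#' CAZy family the prediction originates from, serialized as `"EC;FAMILY"`
#' (e.g. `"3.2.1.4;GH5"`). The same EC in two families is two distinct keys;
#' subfamily labels never participate in key identity.
#'
#' @param ec Canonical EC label(s) (see [normalize_ec()]).
#' @param family Parent CAZy family label(s), e.g. `"GH5"`.
#' @return Character vector of observation keys.
#' @examples
#' make_observation_key("3.2.1.4", "GH5")  # "3.2.1.4;GH5"
#' @export
make_observation_key <- function(ec, family) {
  ec <- normalize_ec(ec)
  bad <- !grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$", family)
  if (any(bad)) {
    stop("invalid CAZy family label: '", family[which(bad)[1]], "'", call. = FALSE)
  }
  paste(ec, family, sep = ";")
}

#' Default excluded-family set
#'
#' All glycosyl transferase families (matched by the `GT` prefix) plus the
#' LPMO AA families in [LPMO_FAMILIES]. Exclusion by prefix is encoded with
#' the sentinel `"GT*"`.
#'
#' @return Character vector of family labels / prefix sentinels.
#' @export
default_excluded_families <- function() c("GT*", LPMO_FAMILIES)

family_is_excluded <- function(family, excluded) {
  prefixes <- sub("\\*$", "", excluded[endsWith(excluded, "*")])
  exact <- excluded[!endsWith(excluded, "*")]
  out <- family %in% exact
  for (p in prefixes) out <- out | startsWith(family, p)
  out
}

#' Extract Function;Family observation instances from annotation records
#'
#' Each distinct (protein, EC, family) triple over non-excluded families
#' yields exactly one observation instance: a protein carrying two EC
#' predictions yields two instances with distinct keys, duplicate identical
#' annotation rows collapse to one instance, records with no EC prediction
#' (e.g. CBM-only annotations) yield nothing, and subfamily labels are
#' collapsed to their parent family before key construction.
#'
#' @param records Annotation data frame from [read_annotations()] (columns
#'   `genome_id`, `protein_id`, `family`, `subfamily`, `ec_labels`
#'   list-column).
#' @param excluded_families Family labels to drop; `"GT*"`-style entries
#'   exclude by prefix. Defaults to all GT families plus the LPMO list.
#' @return Data frame of observation instances with columns `genome_id`,
#'   `protein_id`, `ec`, `family`, `key`, in first-appearance order.
#' @export
extract_observations <- function(records,
                                 excluded_families = default_excluded_families()) {
  stopifnot(is.data.frame(records))
  empty <- data.frame(genome_id = character(0), protein_id = character(0),
                      ec = character(0), family = character(0),
                      key = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  n_ec <- lengths(records$ec_labels)
  keep <- n_ec > 0L & !family_is_excluded(records$family, excluded_families)
  if (!any(keep)) return(empty)
  rec <- records[keep, , drop = FALSE]
  n_ec <- n_ec[keep]
  inst <- data.frame(
    genome_id = rep(rec$genome_id, n_ec),
    protein_id = rep(rec$protein_id, n_ec),
    ec = normalize_ec(unlist(rec$ec_labels, use.names = FALSE)),
    family = rep(rec$family, n_ec),
    stringsAsFactors = FALSE
  )
  inst$key <- paste(inst$ec, inst$family, sep = ";")
  dup <- duplicated(paste(inst$genome_id, inst$protein_id, inst$key, sep = "\r"))
  rownames(inst) <- NULL
  inst[!dup, , drop = FALSE]
}
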