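# Shared fixtures and independent brute-force oracles. The oracles mirror
# the scoring definitions by explicit set construction and nested loops,
# deliberately sharing no code with the package internals they check.

lpmo_list <- c("AA9", "AA10", "AA11", "AA13", "AA14", "AA15", "AA16", "AA17")

# Collapse a raw family label to its parent the blunt way.
bf_parent <- function(fam) sub("[_:].*$", "", fam)

bf_norm_ec <- function(ec) sub("\\.-$", ".*", ec)

# Enumerate distinct (protein, EC, family) triples over non-excluded
# families from raw annotation rows (genome_id, protein_id, family, ec;
# one EC per row).
bf_triples <- function(rows) {
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(rows))) {
    fam <- bf_parent(rows$family[i])
    if (startsWith(fam, "GT") || fam %in% lpmo_list) next
    ec <- rows$ec[i]
    if (is.na(ec) || !nzchar(ec)) next
    ec <- bf_norm_ec(ec)
    tag <- paste(rows$genome_id[i], rows$protein_id[i], ec, fam, sep = "|")
    if (tag %in% seen) next
    seen <- c(seen, tag)
    out[[length(out) + 1L]] <- data.frame(genome_id = rows$genome_id[i],
                                          protein_id = rows$protein_id[i],
                                          ec = ec, family = fam,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), protein_id = character(0),
                      ec = character(0), family = character(0)))
  }
  do.call(rbind, out)
}

# Resolve one (ec, family) pair against a plain map data frame
# (ec_pattern, family_pattern, substrates comma-joined), tier by tier.
bf_substrates <- function(ec, fam, map_df) {
  tier_of <- function(j) {
    e <- map_df$ec_pattern[j] == ec
    f <- map_df$family_pattern[j] == fam
    ew <- map_df$ec_pattern[j] == "*"
    fw <- map_df$family_pattern[j] == "*"
    if (e && f) 1 else if (e && fw) 2 else if (ew && f) 3 else if (ew && fw) 4 else NA
  }
  tiers <- vapply(seq_len(nrow(map_df)), tier_of, numeric(1))
  if (all(is.na(tiers))) return(character(0))
  j <- which(tiers == min(tiers, na.rm = TRUE))[1]
  trimws(strsplit(map_df$substrates[j], ",")[[1]])
}

# Full brute-force profile for one genome's raw annotation rows.
bf_profile <- function(rows, map_df) {
  tri <- bf_triples(rows)
  subs4 <- c("cellulose", "pectin", "xylan", "lignin")
  red <- uni <- setNames(numeric(4), subs4)
  seen_keys <- character(0)
  for (i in seq_len(nrow(tri))) {
    ss <- bf_substrates(tri$ec[i], tri$family[i], map_df)
    if (length(ss) == 0L) next
    w <- 1 / length(ss)
    for (s in ss) red[s] <- red[s] + w
    key <- paste(tri$ec[i], tri$family[i], sep = ";")
    if (!(key %in% seen_keys)) {
      seen_keys <- c(seen_keys, key)
      for (s in ss) uni[s] <- uni[s] + w
    }
  }
  list(redundant = red, unique = uni)
}

# Random raw annotation rows + a consistent random map, for property tests.
random_fixture <- function(seed, n_rows = 40) {
  set.seed(seed)
  fams <- c("GH5", "GH5_7", "GH7", "GH10", "PL1", "CE1", "AA2", "GT2", "AA9", "CBM1")
  ecs <- c("3.2.1.4", "3.2.1.8", "3.2.1.15", "1.10.3.2", "3.2.1.-", "4.2.2.2", "")
  rows <- data.frame(
    genome_id = sample(c("gA", "gB"), n_rows, replace = TRUE),
    protein_id = sprintf("p%02d", sample.int(25, n_rows, replace = TRUE)),
    family = sample(fams, n_rows, replace = TRUE),
    ec = sample(ecs, n_rows, replace = TRUE),
    stringsAsFactors = FALSE
  )
  subs4 <- c("cellulose", "pectin", "xylan", "lignin")
  pats <- expand.grid(ec_pattern = c(unique(bf_norm_ec(ecs[nzchar(ecs)])), "*"),
                      family_pattern = c("GH5", "GH7", "PL1", "*"),
                      stringsAsFactors = FALSE)
  keep <- sample(nrow(pats), min(nrow(pats), 10))
  map_df <- pats[keep, , drop = FALSE]
  map_df$substrates <- vapply(seq_len(nrow(map_df)), function(i) {
    paste(sample(subs4, sample(1:2, 1)), collapse = ",")
  }, character(1))
  rownames(map_df) <- NULL
  list(rows = rows, map_df = map_df)
}

# Package-side objects from the raw fixture.
fixture_records <- function(rows) as_annotation_records(rows)

fixture_map <- function(map_df) {
  m <- map_df[, c("ec_pattern", "family_pattern")]
  m$substrates <- lapply(strsplit(map_df$substrates, ","), trimws)
  class(m) <- c("substrate_map", class(m))
  m
}

write_fixture_tsv <- function(df, dir = tempdir(), name = "fixture.tsv") {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent N50 oracle: try every candidate length L in the list and take
# the largest whose >=L contigs cover half the total.
bf_n50 <- function(lens) {
  total <- sum(lens)
  ok <- vapply(sort(unique(lens), decreasing = TRUE),
               function(L) sum(lens[lens >= L]) >= total / 2, logical(1))
  sort(unique(lens), decreasing = TRUE)[which(ok)[1]]
}
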