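cellulose_map <- function() {
  m <- data.frame(ec_pattern = c("3.2.1.4", "3.1.1.73"),
                  family_pattern = "*", stringsAsFactors = FALSE)
  m$substrates <- list("cellulose", c("cellulose", "xylan"))
  class(m) <- c("substrate_map", class(m))
  m
}

inst_df <- function(protein, key, genome = "gA") {
  parts <- strsplit(key, ";", fixed = TRUE)
  data.frame(genome_id = rep_len(genome, length(protein)), protein_id = protein,
             ec = vapply(parts, `[`, character(1), 1),
             family = vapply(parts, `[`, character(1), 2),
             key = key, stringsAsFactors = FALSE)
}

test_that("redundant counts instances, unique counts distinct keys", {
  p <- score_genome(inst_df(c("p1", "p2", "p3"), rep("3.2.1.4;GH5", 3)),
                    cellulose_map())
  expect_equal(p$redundant[["cellulose"]], 3)
  expect_equal(p$unique[["cellulose"]], 1)
  expect_equal(p$total_redundant, 3)
})

test_that("a dual-substrate key contributes one half to each substrate", {
  p <- score_genome(inst_df("p1", "3.1.1.73;CE1"), cellulose_map())
  expect_equal(p$redundant[["cellulose"]], 0.5)
  expect_equal(p$redundant[["xylan"]], 0.5)
  expect_equal(p$total_redundant, 1)
})

test_that("degenerate inputs score cleanly", {
  p <- score_genome(inst_df(character(0), character(0)), cellulose_map())
  expect_true(all(p$redundant == 0) && all(p$unique == 0))
  expect_error(score_genome(rbind(inst_df("p1", "3.2.1.4;GH5", "gA"),
                                  inst_df("p1", "3.2.1.4;GH5", "gB")),
                            cellulose_map()),
               "multiple genomes")
})

test_that("profiles match the brute-force set/sum oracle on random fixtures", {
  for (seed in 1:25) {
    fx <- random_fixture(seed, n_rows = 50)
    map <- fixture_map(fx$map_df)
    inst <- extract_observations(fixture_records(fx$rows))
    for (g in unique(fx$rows$genome_id)) {
      got <- score_genome(inst[inst$genome_id == g, , drop = FALSE], map)
      want <- bf_profile(fx$rows[fx$rows$genome_id == g, , drop = FALSE],
                         fx$map_df)
      expect_equal(got$redundant, want$redundant[names(got$redundant)],
                   label = sprintf("seed %d genome %s redundant", seed, g))
      expect_equal(got$unique, want$unique[names(got$unique)],
                   label = sprintf("seed %d genome %s unique", seed, g))
      # invariants: U_s <= R_s, conservation of mapped instance weight
      expect_true(all(got$unique <= got$redundant + 1e-12))
    }
  }
})

test_that("total capacity is the sum of the four substrate scores", {
  prof <- data.frame(genome_id = "g", r_cellulose = 248, r_pectin = 85,
                     r_xylan = 208, r_lignin = 0, total_redundant = 541,
                     u_cellulose = 0, u_pectin = 0, u_xylan = 0, u_lignin = 0,
                     total_unique = 0)
  expect_equal(total_capacity(prof[1, ]), 541)
  prof2 <- within(prof, {r_cellulose <- 91; r_pectin <- 204; r_xylan <- 50
                         r_lignin <- 149})
  expect_equal(total_capacity(prof2[1, ]), 494)
  zero <- within(prof, {r_cellulose <- 0; r_pectin <- 0; r_xylan <- 0
                        r_lignin <- 0})
  expect_equal(total_capacity(zero[1, ]), 0)
})

test_that("association sums add the chosen mode over a substrate combination", {
  prof <- data.frame(genome_id = "g", r_cellulose = 91, r_pectin = 204,
                     r_xylan = 50, r_lignin = 149, total_redundant = 494,
                     u_cellulose = 1, u_pectin = 2, u_xylan = 3, u_lignin = 4,
                     total_unique = 10)
  expect_equal(association_sum(prof[1, ], c("pectin", "lignin")), 353)
  expect_equal(association_sum(prof[1, ], SUBSTRATES), total_capacity(prof[1, ]))
  expect_equal(association_sum(prof[1, ], c("pectin", "lignin"), mode = "unique"), 6)
  expect_error(association_sum(prof[1, ], c("pectin", "granite")), "granite")
})

test_that("RMS ratios round half-up and flag extremes from the unrounded value", {
  r <- rms(c(208, 204, 108, 5, 0), c(16, 24, 22, 5, 0))
  expect_equal(r$ratio_rounded[1:4], c(13.0, 8.5, 4.9, 1.0))
  expect_equal(r$flag[1:4], c("high", "high", "none", "low"))
  # undefined: NA marker, never zero or infinity
  expect_true(is.na(r$ratio[5]))
  expect_equal(r$flag[5], "none")
  expect_true(is.na(rms(3, 0)$ratio))
  expect_error(rms(-1, 2), "non-negative")
})

test_that("RMS is at least one whenever the unique score is positive", {
  for (seed in 1:20) {
    fx <- random_fixture(seed)
    prof <- score_genomes(extract_observations(fixture_records(fx$rows)),
                          fixture_map(fx$map_df))
    tab <- rms_table(prof)
    pos <- !is.na(tab$ratio)
    expect_true(all(tab$ratio[pos] >= 1 - 1e-12), label = sprintf("seed %d", seed))
  }
})

test_that("duplicating every instance doubles R, fixes U, doubles RMS", {
  fx <- random_fixture(8)
  map <- fixture_map(fx$map_df)
  inst <- extract_observations(fixture_records(fx$rows))
  g <- unique(inst$genome_id)[1]
  one <- inst[inst$genome_id == g, , drop = FALSE]
  # duplicate under fresh protein ids so instances are distinct
  two <- one
  two$protein_id <- paste0(two$protein_id, "_dup")
  both <- rbind(one, two)
  p1 <- score_genome(one, map)
  p2 <- score_genome(both, map)
  expect_equal(p2$redundant, 2 * p1$redundant)
  expect_equal(p2$unique, p1$unique)
  pos <- p1$unique > 0
  expect_equal((p2$redundant / p2$unique)[pos], 2 * (p1$redundant / p1$unique)[pos])
})

test_that("mapped instances each contribute exactly unit weight to the total", {
  for (seed in 1:10) {
    fx <- random_fixture(seed)
    map <- fixture_map(fx$map_df)
    inst <- extract_observations(fixture_records(fx$rows))
    mapped <- vapply(inst$key, function(k) length(substrates_for(k, map)) > 0,
                     logical(1))
    prof <- score_genomes(inst, map)
    expect_equal(sum(prof$total_redundant), sum(mapped),
                 label = sprintf("seed %d", seed))
  }
})
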