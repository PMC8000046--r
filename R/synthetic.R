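#' Specify a synthetic genome
#'
#' Describes one genome for the synthetic annotation generator: how many
#' distinct observation keys it carries per substrate (its unique scores),
#' the mean gene-copy redundancy per key and substrate, and what fraction
#' of keys act on two substrates at once.
#'
#' @param genome_id Unique genome identifier.
#' @param species,genus,class,phylum Taxonomy written into the synthetic
#'   metadata table.
#' @param u Named integer vector over [SUBSTRATES]: distinct observation
#'   keys per substrate (the ground-truth unique scores).
#' @param m Named numeric vector over [SUBSTRATES], each >= 1: mean copies
#'   per key. Copy numbers are drawn as `Poisson(m - 1) + 1` so every key
#'   present in the genome has at least one gene.
#' @param dual_fraction Fraction in `[0, 1]` of keys shared between the
#'   cellulose and xylan pools (counting one half for each substrate).
#' @param seed Integer seed making the genome fully reproducible.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_id, species = genome_id, genus = "Genus",
                        class = "Sordariomycetes", phylum = "Ascomycota",
                        u = c(cellulose = 10, pectin = 10, xylan = 10, lignin = 10),
                        m = c(cellulose = 1, pectin = 1, xylan = 1, lignin = 1),
                        dual_fraction = 0, seed = 1L) {
  u <- u[SUBSTRATES]; m <- m[SUBSTRATES]
  names(u) <- names(m) <- SUBSTRATES
  u[is.na(u)] <- 0; m[is.na(m)] <- 1
  stopifnot(all(u >= 0), all(u == round(u)), all(m >= 1),
            dual_fraction >= 0, dual_fraction <= 1, nzchar(genome_id))
  structure(list(genome_id = genome_id, species = species, genus = genus,
                 class = class, phylum = phylum, u = u, m = m,
                 dual_fraction = dual_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

# Deterministic synthetic key pools. ECs use the fictitious leading fields
# 8 (dual cellulose+xylan keys) and 9 (single-substrate keys, second field
# indexing the substrate), which cannot collide with real EC space or the
# shipped substrate map.
synthetic_key_pool <- function(substrate, pool_size) {
  s_idx <- match(substrate, SUBSTRATES)
  i <- seq_len(pool_size)
  fam_class <- c(cellulose = "GH", pectin = "PL", xylan = "GH", lignin = "AA")[[substrate]]
  data.frame(
    ec = sprintf("9.%d.%d.%d", s_idx, 1 + (i - 1) %/% 500, 1 + (i - 1) %% 500),
    family = sprintf("%s%d", fam_class, 900 + (i - 1) %% 40),
    stringsAsFactors = FALSE
  )
}

synthetic_dual_pool <- function(pool_size) {
  i <- seq_len(pool_size)
  data.frame(
    ec = sprintf("8.1.%d.%d", 1 + (i - 1) %/% 500, 1 + (i - 1) %% 500),
    family = sprintf("GH%d", 950 + (i - 1) %% 40),
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic genome
#'
#' Draws the spec'd number of distinct observation keys per substrate from
#' deterministic synthetic key pools, emits `Poisson(m_s - 1) + 1` protein
#' copies per key, and emits the matching substrate-map entries. Dual
#' cellulose+xylan keys appear in both substrate pools with weight one half
#' each; their count is rounded down to an even number so the half-weights
#' sum to whole keys and the scored unique score recovers `u_s` exactly.
#'
#' @param spec A [genome_spec()].
#' @param pool_size Keys available per substrate pool.
#' @return List with `annotations` (annotation record rows), `map_entries`
#'   (substrate-map rows for every key used), and `truth` (ground-truth
#'   `u`, realized `r`, and their ratio `rms` per substrate).
#' @export
generate_genome <- function(spec, pool_size = 5000L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  d <- 2L * floor(spec$dual_fraction * min(spec$u["cellulose"], spec$u["xylan"]) / 2)
  n_single <- spec$u
  n_single["cellulose"] <- n_single["cellulose"] - d / 2
  n_single["xylan"] <- n_single["xylan"] - d / 2
  if (any(n_single > pool_size) || d > pool_size) {
    stop("requested more distinct keys than the pool size (", pool_size, ")",
         call. = FALSE)
  }

  keys <- list()   # per drawn key: ec, family, substrates, weight per substrate
  for (s in SUBSTRATES) {
    if (n_single[[s]] == 0) next
    pool <- synthetic_key_pool(s, pool_size)
    pick <- pool[sample.int(pool_size, n_single[[s]]), , drop = FALSE]
    pick$substrates <- s
    pick$m <- spec$m[[s]]
    keys[[s]] <- pick
  }
  if (d > 0) {
    pool <- synthetic_dual_pool(pool_size)
    pick <- pool[sample.int(pool_size, d), , drop = FALSE]
    pick$substrates <- "cellulose,xylan"
    pick$m <- spec$m[["cellulose"]]  # dual keys ride the cellulose multiplier
    keys[["dual"]] <- pick
  }
  keys <- do.call(rbind, keys)

  r <- stats::setNames(numeric(length(SUBSTRATES)), SUBSTRATES)
  if (is.null(keys) || nrow(keys) == 0L) {
    ann <- data.frame(genome_id = character(0), protein_id = character(0),
                      family = character(0), ec = character(0),
                      stringsAsFactors = FALSE)
    map_entries <- data.frame(ec_pattern = character(0),
                              family_pattern = character(0),
                              substrates = character(0), stringsAsFactors = FALSE)
  } else {
    copies <- stats::rpois(nrow(keys), keys$m - 1) + 1L
    for (i in seq_len(nrow(keys))) {
      subs <- strsplit(keys$substrates[i], ",", fixed = TRUE)[[1]]
      r[subs] <- r[subs] + copies[i] / length(subs)
    }
    ann <- data.frame(
      genome_id = spec$genome_id,
      protein_id = sprintf("%s_p%05d", spec$genome_id, seq_len(sum(copies))),
      family = rep(keys$family, copies),
      ec = rep(keys$ec, copies),
      stringsAsFactors = FALSE
    )
    map_entries <- data.frame(ec_pattern = keys$ec, family_pattern = "*",
                              substrates = keys$substrates,
                              stringsAsFactors = FALSE)
  }
  truth_u <- as.numeric(spec$u)
  names(truth_u) <- SUBSTRATES
  list(annotations = ann,
       map_entries = map_entries,
       truth = list(genome_id = spec$genome_id, u = truth_u, r = r,
                    rms = ifelse(truth_u > 0, r / truth_u, NA_real_)))
}

#' Generate a full synthetic input bundle for a cohort
#'
#' Merges per-genome synthetic annotations into one table with consistent
#' metadata, a deduplicated substrate map, and assembly candidates whose
#' coverage and contig lengths make the intended representative known.
#'
#' @param specs List of [genome_spec()]s with distinct genome ids.
#' @param seed Master seed; each genome is generated from a seed derived
#'   from it, so the whole bundle is reproducible.
#' @param pool_size Keys available per substrate pool.
#' @return List with `annotations`, `metadata`, `map` (a `substrate_map`),
#'   `assemblies`, `expected_representative` (accession per species) and
#'   `truth` (per-genome ground truth).
#' @export
generate_cohort <- function(specs, seed = 1L, pool_size = 5000L) {
  ids <- vapply(specs, function(s) s$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id in cohort specs: '", ids[anyDuplicated(ids)], "'",
         call. = FALSE)
  }
  gens <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp$seed <- as.integer(seed * 1000L + i)
    generate_genome(sp, pool_size = pool_size)
  })
  annotations <- do.call(rbind, lapply(gens, `[[`, "annotations"))
  map_df <- unique(do.call(rbind, lapply(gens, `[[`, "map_entries")))
  map <- map_df
  map$substrates <- strsplit(map_df$substrates, ",", fixed = TRUE)
  class(map) <- c("substrate_map", class(map))
  rownames(map) <- NULL
  metadata <- data.frame(
    genome_id = ids,
    species = vapply(specs, `[[`, character(1), "species"),
    genus = vapply(specs, `[[`, character(1), "genus"),
    class = vapply(specs, `[[`, character(1), "class"),
    phylum = vapply(specs, `[[`, character(1), "phylum"),
    accession = paste0("SYN_", ids, ".1"),
    stringsAsFactors = FALSE
  )
  # Two assembly candidates per species; the ".1" accession is constructed
  # to win on coverage * N50.
  set.seed(as.integer(seed))
  assemblies <- do.call(rbind, lapply(ids, function(g) {
    winner_cov <- stats::runif(1, 40, 80)
    data.frame(
      species_taxid = g,
      accession = paste0("SYN_", g, c(".1", ".2")),
      coverage = c(winner_cov, winner_cov / 2),
      n50 = c(50000, 40000),
      stringsAsFactors = FALSE
    )
  }))
  assemblies$contig_lengths <- rep(list(NULL), nrow(assemblies))
  truth <- lapply(gens, `[[`, "truth")
  names(truth) <- ids
  list(annotations = annotations, metadata = metadata, map = map,
       assemblies = assemblies,
       expected_representative = stats::setNames(paste0("SYN_", ids, ".1"), ids),
       truth = truth)
}

#' Write a synthetic cohort bundle to disk
#'
#' Serializes the bundle exactly in the input formats the readers consume,
#' so a written bundle can drive the full pipeline from files.
#'
#' @param bundle Cohort bundle from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(bundle$annotations, "annotations.tsv")
  write_tsv(bundle$metadata, "metadata.tsv")
  map_out <- data.frame(ec_pattern = bundle$map$ec_pattern,
                        family_pattern = bundle$map$family_pattern,
                        substrates = vapply(bundle$map$substrates, paste,
                                            character(1), collapse = ","),
                        stringsAsFactors = FALSE)
  write_tsv(map_out, "substrate_map.tsv")
  asm <- bundle$assemblies[, c("species_taxid", "accession", "coverage", "n50")]
  write_tsv(asm, "assemblies.tsv")
  invisible(dir)
}

#' Read a cohort spec file
#'
#' YAML list of genome specs (fields as in [genome_spec()], with `u` and
#' `m` as named maps).
#'
#' @param path YAML file path.
#' @return List of `genome_spec`s.
#' @export
read_cohort_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    genome_spec(genome_id = x$genome_id,
                species = x$species %||% x$genome_id,
                genus = x$genus %||% "Genus",
                class = x$class %||% "Sordariomycetes",
                phylum = x$phylum %||% "Ascomycota",
                u = unlist(x$u), m = unlist(x$m %||% list(cellulose = 1)),
                dual_fraction = x$dual_fraction %||% 0,
                seed = x$seed %||% 1L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild a cohort from a per-substrate count table
#'
#' Reconstructs annotation records and a matching substrate map whose
#' scored profiles reproduce a stated per-substrate observation count
#' table, so that aggregate arithmetic (totals, association sums,
#' rankings) can be verified end-to-end through the real extract -> map ->
#' score path. In `"redundant"` mode each count c becomes c protein copies
#' of one key (capacity c per substrate); in `"unique"` mode it becomes c
#' distinct keys carried once each (diversity c per substrate).
#'
#' @param counts Data frame with columns `genome_id`, `species`, `genus`,
#'   `class`, `phylum` and one integer column per substrate in
#'   [SUBSTRATES], or the path of such a TSV.
#' @param mode Whether the counts are redundant (capacity) or unique
#'   (diversity) observation counts.
#' @return List with `records` (annotation records as returned by
#'   [read_annotations()]), `metadata` and `map`.
#' @export
cohort_from_counts <- function(counts, mode = c("redundant", "unique")) {
  mode <- match.arg(mode)
  if (is.character(counts)) {
    counts <- read_tsv_checked(counts, required = c("genome_id", "species",
                                                    "genus", "class", "phylum",
                                                    SUBSTRATES))
  }
  pool_size <- max(2L, suppressWarnings(max(vapply(
    SUBSTRATES, function(s) max(as.numeric(counts[[s]])), numeric(1)))))
  ann <- list()
  used <- stats::setNames(integer(length(SUBSTRATES)), SUBSTRATES)
  for (g in seq_len(nrow(counts))) {
    gid <- counts$genome_id[g]
    p <- 0L
    for (s in SUBSTRATES) {
      c_s <- as.integer(counts[[s]][g])
      if (is.na(c_s) || c_s == 0L) next
      pool <- synthetic_key_pool(s, pool_size)
      if (mode == "redundant") {
        keys <- pool[rep(1L, c_s), , drop = FALSE]
        used[s] <- max(used[s], 1L)
      } else {
        keys <- pool[seq_len(c_s), , drop = FALSE]
        used[s] <- max(used[s], c_s)
      }
      ann[[length(ann) + 1L]] <- data.frame(
        genome_id = gid,
        protein_id = sprintf("%s_%s_p%04d", gid, s, p + seq_len(c_s)),
        family = keys$family, ec = keys$ec, stringsAsFactors = FALSE)
      p <- p + c_s
    }
  }
  ann <- do.call(rbind, ann)
  records <- data.frame(genome_id = ann$genome_id, protein_id = ann$protein_id,
                        family = ann$family, subfamily = NA_character_,
                        stringsAsFactors = FALSE)
  records$ec_labels <- as.list(ann$ec)
  map_rows <- list()
  for (s in SUBSTRATES) {
    if (used[s] == 0L) next
    pool <- synthetic_key_pool(s, pool_size)
    map_rows[[s]] <- data.frame(ec_pattern = pool$ec[seq_len(used[s])],
                                family_pattern = "*", stringsAsFactors = FALSE)
    map_rows[[s]]$substrates <- rep(list(s), used[s])
  }
  map <- do.call(rbind, map_rows)
  rownames(map) <- NULL
  class(map) <- c("substrate_map", class(map))
  metadata <- counts[, c("genome_id", "species", "genus", "class", "phylum")]
  metadata$accession <- paste0("REF_", metadata$genome_id)
  list(records = records, metadata = metadata, map = map)
}
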