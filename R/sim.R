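#' Configuration for the synthetic phage-IP cohort generator
#'
#' Bundles and validates every knob of the simulator. The defaults
#' describe a study-like cohort: a near-uniform library with a small
#' undetected fraction, overdispersed mock immunoprecipitations, an
#' allergic group with broad wheat IgE/IgG reactivity, a sensitized group
#' with wheat IgG but narrow IgE, a non-allergic group whose IgG
#' frequently recognises a three-isoform "discriminator epitope" family,
#' and an oral-immunotherapy arm with paired pre/post timepoints.
#'
#' @param n_proteins Number of background proteins in the synthetic
#'   proteome (the three discriminator-epitope isoform proteins are added
#'   on top).
#' @param protein_length_range Integer range (min, max) of background
#'   protein lengths in residues.
#' @param n_organisms Number of organisms; the first is always `"wheat"`.
#' @param abundance_sigma log10-scale SD of clone abundance in the
#'   packaged library.
#' @param dropout_fraction Fraction of clones absent from the library
#'   (never detected).
#' @param n_mocks Number of mock (no-serum) immunoprecipitations.
#' @param dispersion Negative binomial dispersion phi (variance
#'   `mu + phi mu^2`); 0 gives Poisson counts.
#' @param depth Reads per sample.
#' @param groups List of group specifications; each a list with `name`,
#'   `n_samples`, per-isotype reactivity specs `ige`/`igg` (lists with
#'   `organism`, `n_peptides`, `fc_meanlog`, `fc_sdlog`) and
#'   `epitope_rate` (named numeric, probability per isotype that a sample
#'   reacts with the discriminator epitope family).
#' @param n_replicate_pairs Technical replicate pairs added for the first
#'   samples of the first group (shared fold changes, independent noise).
#' @param oit `NULL`, or a list describing the oral-immunotherapy arm:
#'   `group`, `n_subjects`, `ige_loss_fraction` (fraction of IgE-reactive
#'   peptides cleared after treatment), `igg_gain_fraction` (new
#'   IgG-reactive wheat peptides gained, as a fraction of the baseline
#'   set), `purothionin_like_gain` (logical: treated subjects gain IgG
#'   reactivity to the epitope family), `gain_rate` (probability of that
#'   gain per subject).
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return A validated `allerscan_sim_config` list.
#' @export
sim_config <- function(n_proteins = 60,
                       protein_length_range = c(100, 400),
                       n_organisms = 8,
                       abundance_sigma = 0.5,
                       dropout_fraction = 0.042,
                       n_mocks = 8,
                       dispersion = 0.02,
                       depth = 1e6,
                       groups = default_sim_groups(),
                       n_replicate_pairs = 2,
                       oit = list(group = "allergic", n_subjects = 21,
                                  ige_loss_fraction = 0.5,
                                  igg_gain_fraction = 0.5,
                                  purothionin_like_gain = TRUE,
                                  gain_rate = 0.85),
                       seed = 1L) {
  stopifnot(n_proteins >= 1, length(protein_length_range) == 2,
            protein_length_range[1] >= 20,
            protein_length_range[2] >= protein_length_range[1],
            n_organisms >= 1, abundance_sigma >= 0,
            dropout_fraction >= 0, n_mocks >= 0,
            dispersion >= 0, depth >= 0, n_replicate_pairs >= 0)
  if (dropout_fraction >= 1) {
    stop("dropout_fraction must be < 1", call. = FALSE)
  }
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("group names must be unique", call. = FALSE)
  if (!is.null(oit) && !oit$group %in% nm) {
    stop("oit$group must name one of the groups", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    protein_length_range = as.integer(protein_length_range),
    n_organisms = as.integer(n_organisms),
    abundance_sigma = abundance_sigma,
    dropout_fraction = dropout_fraction,
    n_mocks = as.integer(n_mocks),
    dispersion = dispersion,
    depth = depth,
    groups = groups,
    n_replicate_pairs = as.integer(n_replicate_pairs),
    oit = oit,
    seed = as.integer(seed)
  ), class = "allerscan_sim_config")
}

#' Default group specifications for [sim_config()]
#'
#' Mirrors the cross-sectional cohort structure: 32 wheat-allergic samples
#' with broad, strong wheat IgE and IgG; 27 wheat-sensitized samples with
#' narrow wheat IgE and intermediate IgG; 27 non-allergic samples with
#' essentially no wheat IgE. The discriminator epitope family is IgG
#' reactive at rate 0.7 in the sensitized and non-allergic groups and IgE
#' reactive in 28% of allergic samples.
#' @return List of group specs.
#' @export
default_sim_groups <- function() {
  list(
    list(name = "allergic", n_samples = 32,
         ige = list(organism = "wheat", n_peptides = 25,
                    fc_meanlog = log(20), fc_sdlog = 0.5),
         igg = list(organism = "wheat", n_peptides = 25,
                    fc_meanlog = log(20), fc_sdlog = 0.5),
         epitope_rate = c(ige = 0.28, igg = 0.05)),
    list(name = "sensitized", n_samples = 27,
         ige = list(organism = "wheat", n_peptides = 4,
                    fc_meanlog = log(10), fc_sdlog = 0.5),
         igg = list(organism = "wheat", n_peptides = 10,
                    fc_meanlog = log(15), fc_sdlog = 0.5),
         epitope_rate = c(ige = 0.02, igg = 0.7)),
    list(name = "non_allergic", n_samples = 27,
         ige = list(organism = "any", n_peptides = 2,
                    fc_meanlog = log(8), fc_sdlog = 0.5),
         igg = list(organism = "wheat", n_peptides = 2,
                    fc_meanlog = log(10), fc_sdlog = 0.5),
         epitope_rate = c(ige = 0.02, igg = 0.7))
  )
}

aa_letters <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(aa_letters(), len, replace = TRUE), collapse = "")
}

#' Generate the synthetic allergen proteome and its tiled library
#'
#' Background proteins are random sequences assigned round-robin to
#' organisms (organism 1 is `"wheat"`). Three near-identical 56-residue
#' "purothionin-like" isoform proteins sharing a conserved core are
#' appended to wheat; their single tiles form the discriminator epitope
#' family and share 7-mers, so they become one connected component in the
#' homology graph.
#'
#' @param config An `allerscan_sim_config`.
#' @return List with `proteins` (tibble), `annotation` (tile tibble) and
#'   `epitope_ids` (tile ids of the discriminator family).
#' @export
simulate_proteome <- function(config) {
  set.seed(config$seed)
  orgs <- c("wheat", if (config$n_organisms > 1)
    paste0("organism_", seq_len(config$n_organisms - 1)))
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]),
                 config$n_proteins, replace = TRUE)
  proteins <- tibble::tibble(
    protein_id = sprintf("prot%03d", seq_len(config$n_proteins)),
    organism = rep(orgs, length.out = config$n_proteins),
    group = NA_character_,
    sequence = vapply(lens, random_protein, character(1))
  )
  # three isoforms: identical 56-mer with two substitutions each outside
  # the conserved core at positions 20..33
  base_iso <- random_protein(56)
  core <- 20:33
  iso <- vapply(1:3, function(i) {
    s <- strsplit(base_iso, "")[[1]]
    if (i > 1) {
      pos <- sample(setdiff(seq_len(56), core), 2)
      s[pos] <- vapply(s[pos],
                       function(a) sample(setdiff(aa_letters(), a), 1),
                       character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  proteins <- dplyr::bind_rows(proteins, tibble::tibble(
    protein_id = paste0("purothionin_iso", 1:3),
    organism = "wheat", group = NA_character_, sequence = iso
  ))
  annotation <- tile_proteins(proteins) |>
    dplyr::rename(clone_id = "tile_id")
  list(proteins = proteins,
       annotation = annotation,
       epitope_ids = annotation$clone_id[
         startsWith(annotation$protein_id, "purothionin_iso")])
}

#' Simulate library clone abundances
#'
#' Clone proportions are log-normal on the log10 scale with SD
#' `abundance_sigma`; an exact `dropout_fraction` of clones is set to zero
#' (absent from the packaged library) and the rest renormalised.
#'
#' @param n_clones Number of clones.
#' @param config An `allerscan_sim_config` (uses `abundance_sigma`,
#'   `dropout_fraction`, `seed`).
#' @return Numeric proportion vector summing to 1 (zeros for dropouts).
#' @export
simulate_library <- function(n_clones, config) {
  if (config$dropout_fraction >= 1) {
    stop("dropout_fraction must be < 1", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  p <- 10^stats::rnorm(n_clones, 0, config$abundance_sigma)
  n_drop <- round(config$dropout_fraction * n_clones)
  if (n_drop > 0) p[sample.int(n_clones, n_drop)] <- 0
  p / sum(p)
}

#' Simulate one immunoprecipitation's read counts
#'
#' Counts are negative binomial around `depth` times the renormalised
#' product of library proportions and enrichment fold changes: enrichment
#' of some clones competitively depletes the rest, as in real sequencing.
#'
#' @param proportions Library clone proportions.
#' @param enrichment_fc Fold-change vector aligned to `proportions`
#'   (all 1 for a mock IP).
#' @param depth Target total reads.
#' @param dispersion NB dispersion phi; 0 gives Poisson draws.
#' @param seed Optional seed for this draw.
#' @return Integer count vector.
#' @export
simulate_ip <- function(proportions, enrichment_fc = rep(1, length(proportions)),
                        depth = 1e6, dispersion = 0.1, seed = NULL) {
  stopifnot(length(proportions) == length(enrichment_fc))
  if (any(enrichment_fc < 0)) stop("fold changes must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(proportions)
  if (depth == 0) return(integer(n))
  w <- proportions * enrichment_fc
  mu <- depth * w / sum(w)
  if (dispersion <= 0) {
    as.integer(stats::rpois(n, mu))
  } else {
    as.integer(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
  }
}

# draw one sample's reactive set and fold changes
draw_reactivity <- function(spec, annotation, epitope_ids, epitope_rate,
                            fc_epitope_meanlog) {
  pool <- if (identical(spec$organism, "any")) annotation$clone_id
          else annotation$clone_id[annotation$organism == spec$organism]
  pool <- setdiff(pool, epitope_ids)
  n <- min(spec$n_peptides, length(pool))
  ids <- if (n > 0) sample(pool, n) else character(0)
  fc <- stats::setNames(exp(stats::rnorm(n, spec$fc_meanlog, spec$fc_sdlog)),
                        ids)
  if (stats::runif(1) < epitope_rate) {
    efc <- exp(stats::rnorm(length(epitope_ids), fc_epitope_meanlog, 0.3))
    fc <- c(fc, stats::setNames(efc, epitope_ids))
  }
  fc
}

fc_vector <- function(fc_named, clone_ids) {
  v <- rep(1, length(clone_ids))
  names(v) <- clone_ids
  v[names(fc_named)] <- pmax(fc_named, 0)
  unname(v)
}

#' Simulate a complete phage-IP cohort with ground truth
#'
#' Generates the synthetic proteome and library, mock IPs, per-sample
#' IgE/IgG IPs with group-structured reactive sets, technical replicates,
#' and paired pre/post oral-immunotherapy timepoints. Treated subjects
#' lose a fraction of their IgE-reactive peptides, gain new IgG-reactive
#' wheat peptides, and (at `gain_rate`) gain IgG reactivity to the
#' discriminator epitope family.
#'
#' The returned ground truth records every planted fold change and the
#' library proportions; analysis stages must never read it.
#'
#' @param config An `allerscan_sim_config`.
#' @return An `allerscan_cohort` list: `counts` (wide tibble, `clone_id`
#'   plus one column per sample), `meta` (sample metadata tibble),
#'   `annotation` (clone annotation), `epitope_ids`, `truth` (list with
#'   `proportions` and long-format `reactivity`), and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "allerscan_sim_config"))
  prot <- simulate_proteome(config)
  ann <- prot$annotation
  n_clones <- nrow(ann)
  props <- simulate_library(n_clones, config)

  set.seed(config$seed + 2L)
  samples <- list()   # sample_id -> named fc vector (reactive only)
  meta <- list()
  add_sample <- function(id, fc_named, group, isotype, timepoint, subject,
                         is_mock = FALSE, replicate_of = NA_character_) {
    samples[[id]] <<- fc_named
    meta[[id]] <<- tibble::tibble(
      sample_id = id, subject_id = subject, group = group,
      isotype = isotype, timepoint = timepoint, is_mock = is_mock,
      replicate_of = replicate_of)
  }
  for (i in seq_len(config$n_mocks)) {
    add_sample(sprintf("mock_%02d", i), stats::setNames(numeric(0), character(0)),
               group = "mock", isotype = NA_character_, timepoint = NA_character_,
               subject = NA_character_, is_mock = TRUE)
  }

  oit <- config$oit
  for (g in config$groups) {
    treated_n <- if (!is.null(oit) && oit$group == g$name) oit$n_subjects else 0
    for (s in seq_len(g$n_samples)) {
      subject <- sprintf("%s_%02d", g$name, s)
      for (iso in c("ige", "igg")) {
        spec <- g[[iso]]
        fc0 <- draw_reactivity(spec, ann, prot$epitope_ids,
                               g$epitope_rate[[iso]], spec$fc_meanlog)
        add_sample(paste0(subject, "_", toupper(iso), "_t0"), fc0,
                   group = g$name, isotype = toupper(iso),
                   timepoint = "t0", subject = subject)
        if (s <= treated_n) {
          fc1 <- fc0
          if (iso == "ige") {
            base_ids <- setdiff(names(fc0), prot$epitope_ids)
            n_lose <- round(oit$ige_loss_fraction * length(base_ids))
            if (n_lose > 0) fc1 <- fc1[!names(fc1) %in% sample(base_ids, n_lose)]
          } else {
            base_ids <- setdiff(names(fc0), prot$epitope_ids)
            pool <- setdiff(ann$clone_id[ann$organism == "wheat"],
                            c(names(fc0), prot$epitope_ids))
            n_gain <- min(round(oit$igg_gain_fraction * max(length(base_ids), 1)),
                          length(pool))
            if (n_gain > 0) {
              new_ids <- sample(pool, n_gain)
              fc1 <- c(fc1, stats::setNames(
                exp(stats::rnorm(n_gain, spec$fc_meanlog, spec$fc_sdlog)),
                new_ids))
            }
            if (isTRUE(oit$purothionin_like_gain) &&
                !any(prot$epitope_ids %in% names(fc1)) &&
                stats::runif(1) < oit$gain_rate) {
              fc1 <- c(fc1, stats::setNames(
                exp(stats::rnorm(length(prot$epitope_ids), spec$fc_meanlog, 0.3)),
                prot$epitope_ids))
            }
          }
          add_sample(paste0(subject, "_", toupper(iso), "_t1"), fc1,
                     group = g$name, isotype = toupper(iso),
                     timepoint = "t1", subject = subject)
        }
      }
    }
  }
  # technical replicates: first IgE samples of the first group
  if (config$n_replicate_pairs > 0) {
    g1 <- config$groups[[1]]$name
    for (r in seq_len(config$n_replicate_pairs)) {
      orig <- sprintf("%s_%02d_IGE_t0", g1, r)
      if (!is.null(samples[[orig]])) {
        add_sample(paste0(orig, "_rep"), samples[[orig]],
                   group = g1, isotype = "IGE", timepoint = "t0",
                   subject = sprintf("%s_%02d", g1, r), replicate_of = orig)
      }
    }
  }

  meta <- dplyr::bind_rows(meta)
  counts <- matrix(0L, n_clones, nrow(meta),
                   dimnames = list(ann$clone_id, meta$sample_id))
  for (id in meta$sample_id) {
    counts[, id] <- simulate_ip(props, fc_vector(samples[[id]], ann$clone_id),
                                depth = config$depth,
                                dispersion = config$dispersion)
  }
  truth_react <- purrr::imap(samples, function(fc, id) {
    if (length(fc) == 0) return(NULL)
    tibble::tibble(sample_id = id, clone_id = names(fc), true_fc = unname(fc))
  }) |> dplyr::bind_rows()

  structure(list(
    counts = tibble::as_tibble(cbind(tibble::tibble(clone_id = ann$clone_id),
                                     tibble::as_tibble(counts))),
    meta = meta,
    annotation = ann,
    epitope_ids = prot$epitope_ids,
    truth = list(
      proportions = tibble::tibble(clone_id = ann$clone_id, proportion = props),
      reactivity = truth_react),
    config = config
  ), class = "allerscan_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `counts.tsv`, `meta.tsv`, `annotation.tsv`,
#' `truth_reactivity.tsv`, `truth_proportions.tsv` and a YAML echo of the
#' configuration.
#'
#' @param cohort An `allerscan_cohort`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(cohort$meta, file.path(out_dir, "meta.tsv"))
  readr::write_tsv(cohort$annotation, file.path(out_dir, "annotation.tsv"))
  readr::write_tsv(cohort$truth$reactivity,
                   file.path(out_dir, "truth_reactivity.tsv"))
  readr::write_tsv(cohort$truth$proportions,
                   file.path(out_dir, "truth_proportions.tsv"))
  cfg <- unclass(cohort$config)
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$epitope_rate <- as.list(g$epitope_rate); g
  })
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write exact-sequence reads for a count vector as FASTQ
#'
#' A minimal writer used to exercise exact-match read counting: each
#' clone's insert contributes `counts[i]` identical reads of its first
#' `read_len` bases, with constant quality. No error model.
#'
#' @param inserts Named character vector of clone insert DNA.
#' @param counts Integer vector aligned to `inserts`.
#' @param path Output path (`.gz` writes gzip).
#' @param read_len Read length; defaults to 50.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(inserts, counts, path, read_len = 50L) {
  stopifnot(length(inserts) == length(counts))
  reads <- rep(substr(unname(inserts), 1L, read_len), counts)
  ids <- paste0("@read", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    writeLines(as.vector(rbind(ids, reads, rep("+", length(reads)), qual)), con)
  }
  invisible(path)
}
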