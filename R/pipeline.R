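# End-to-end orchestration: run every analysis stage against simulated or
# file-based inputs and write a machine-readable report bundle.
#
# The run configuration holds either a `simulate` block (arguments for
# sim_config()) or an `inputs` block (paths to FASTA/TSV/structure files),
# plus thresholds, resample counts and a single master seed. Every
# stochastic stage derives its own sub-seed from the master seed and
# records it in the summary, so any stage can be re-executed independently.

#' Build a run configuration
#'
#' @param simulate Named list of [sim_config()] arguments, or `NULL` when
#'   `inputs` is given.
#' @param inputs Named list of paths: `fasta`, `sites`, optional
#'   `abundance`, `structures` (mapping TSV `accession pdb_path dssp_path
#'   [chain] [offset]`), `annotations`, `patterns`.
#' @param stages Character vector of stages to run, any of `"cooccur"`,
#'   `"proximity"`, `"structure"`, `"windows"`, `"classify"`, `"enrich"`.
#' @param min_fraction Sulfoxide curation threshold (see [curate_metO()]).
#' @param distance_threshold Strict "near" threshold in residues.
#' @param halfwidth Window half-width.
#' @param cluster_radius Radius for phosphosite cluster counts.
#' @param n_samples Resamples per null distribution.
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       stages = c("cooccur", "proximity", "structure",
                                  "windows", "classify", "enrich"),
                       min_fraction = 0.20, distance_threshold = 7,
                       halfwidth = 7, cluster_radius = 10,
                       n_samples = 10000, seed = 1L, out_dir = "results") {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be given")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(min_fraction >= 0, min_fraction <= 1,
            distance_threshold >= 1, halfwidth >= 1, cluster_radius >= 1,
            n_samples >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1, structures = 2, cooccur = 3, proximity = 4,
               windows = 5, classify = 6, enrich = 7)
  (as.double(seed) * 69621 + offsets[[stage]] * 104729) %% 2147483629 + 1
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the inputs, curates the sulfoxide sites, runs the
#' requested stages, writes per-stage TSV outputs plus `summary.json` under
#' `config$out_dir`, and returns the summary invisibly. Identical
#' configuration and seed give an identical bundle.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(schema = "metophos/summary/v1",
                  seed = config$seed,
                  n_samples = config$n_samples,
                  stages = list())

  # --- inputs ---------------------------------------------------------------
  structures <- NULL
  annotations <- NULL
  patterns <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_proteome(do.call(sim_config, args))
    proteins <- sim$proteins
    sites <- sim$sites
    if ("structure" %in% config$stages) {
      structures <- simulate_structures(
        proteins, seed = stage_seed(config$seed, "structures"))
    }
    summary$input <- list(kind = "simulated",
                          sim_seed = args$seed,
                          n_proteins = nrow(proteins))
  } else {
    proteins <- load_proteome(config$inputs$fasta, config$inputs$abundance)
    sites <- load_sites(config$inputs$sites, proteins)
    if (!is.null(config$inputs$structures) &&
        "structure" %in% config$stages) {
      mapping <- readr::read_tsv(config$inputs$structures, comment = "#",
                                 show_col_types = FALSE)
      structures <- read_structures(mapping, proteins)
    }
    if (!is.null(config$inputs$annotations)) {
      annotations <- read_annotations(config$inputs$annotations)
    }
    if (!is.null(config$inputs$patterns)) {
      patterns <- read_patterns(config$inputs$patterns)
    }
    summary$input <- list(kind = "files", fasta = config$inputs$fasta,
                          n_proteins = nrow(proteins))
  }

  sites <- curate_metO(sites, config$min_fraction)
  meto_acc <- unique(sites$accession[sites$kind == "sulfoxide"])
  phospho_acc <- unique(sites$accession[sites$kind == "phospho"])
  write_sites(sites, file.path(config$out_dir, "curated_sites.tsv"))

  # --- co-occurrence --------------------------------------------------------
  if ("cooccur" %in% config$stages && length(meto_acc) > 0) {
    sseed <- stage_seed(config$seed, "cooccur")
    res <- list()
    for (other_kind in c("phospho", "ubiquityl", "acetyl")) {
      other <- unique(sites$accession[sites$kind == other_kind])
      if (length(other) == 0) next
      ct <- cooccurrence_test(proteins, meto_acc, other,
                              n_samples = config$n_samples, seed = sseed)
      res[[other_kind]] <- list(observed = ct$observed, p = ct$p,
                                is_bound = ct$is_bound,
                                null_mean = mean(ct$null$values))
    }
    matched <- NULL
    if (sum(!is.na(proteins$abundance[proteins$accession %in% meto_acc])) >= 4) {
      m <- try(cooccurrence_test(proteins, meto_acc, phospho_acc,
                                 n_samples = config$n_samples, seed = sseed,
                                 matched = TRUE), silent = TRUE)
      if (!inherits(m, "try-error")) {
        matched <- list(observed = m$observed, p = m$p, is_bound = m$is_bound,
                        median_ks_p = stats::median(m$diagnostics$ks_p))
      }
    }
    summary$stages$cooccur <- list(seed = sseed, unmatched = res,
                                   matched_phospho = matched)
  }

  # --- sequence proximity ---------------------------------------------------
  if ("proximity" %in% config$stages && length(meto_acc) > 0) {
    dt <- distance_tables(proteins, sites)
    readr::write_tsv(dt$records,
                     file.path(config$out_dir, "distance_records.tsv"))
    cmp <- try(compare_met_meto(dt$records, "any_pSite",
                                config$distance_threshold), silent = TRUE)
    hist <- cluster_histogram(proteins, sites, config$cluster_radius)
    readr::write_tsv(hist, file.path(config$out_dir, "cluster_counts.tsv"))
    summary$stages$proximity <- list(
      comparison = if (!inherits(cmp, "try-error")) as.list(cmp) else NULL,
      n_records = nrow(dt$records))
  }

  # --- structure ------------------------------------------------------------
  if ("structure" %in% config$stages && !is.null(structures)) {
    sd <- structure_distances(structures, proteins, sites)
    readr::write_tsv(sd, file.path(config$out_dir, "structure_distances.tsv"))
    ok <- !is.na(sd$spatial_dist)
    summary$stages$structure <- list(
      n_met = sum(!sd$met_oxidized), n_metO = sum(sd$met_oxidized),
      mean_spatial_metO = mean(sd$spatial_dist[ok & sd$met_oxidized]),
      mean_spatial_met = mean(sd$spatial_dist[ok & !sd$met_oxidized]),
      mean_seq_metO = mean(sd$seq_dist[sd$met_oxidized], na.rm = TRUE),
      mean_seq_met = mean(sd$seq_dist[!sd$met_oxidized], na.rm = TRUE))
  } else if ("structure" %in% config$stages) {
    summary$stages$structure <- list(skipped = "no structures supplied")
  }

  # --- window statistics ----------------------------------------------------
  if ("windows" %in% config$stages) {
    sseed <- stage_seed(config$seed, "windows")
    aw <- acceptor_windows(proteins, sites, config$halfwidth)
    readr::write_tsv(aw, file.path(config$out_dir, "acceptor_windows.tsv"))
    res <- list()
    for (r in c("S", "T", "Y")) {
      wr <- aw[aw$acceptor_residue == r, , drop = FALSE]
      np <- sum(wr$is_phosphosite)
      if (np == 0 || nrow(wr) == 0) next
      obs <- mean_per_site(wr[wr$is_phosphosite, , drop = FALSE])
      panel <- list(n_acceptors = nrow(wr), n_phosphosites = np,
                    mean_met = obs$mean_met, mean_metO = obs$mean_metO)
      for (statistic in c("n_met", "n_metO")) {
        nd <- acceptor_null(wr, np, statistic, config$n_samples, sseed)
        o <- if (statistic == "n_met") obs$mean_met else obs$mean_metO
        tail <- if (statistic == "n_met") "lower" else "upper"
        ep <- empirical_p(nd, o, tail)
        panel[[paste0("p_", statistic)]] <- ep$p
        panel[[paste0("bound_", statistic)]] <- ep$is_bound
      }
      res[[r]] <- panel
    }
    prof <- try(positional_profile(proteins, sites, "S", config$halfwidth),
                silent = TRUE)
    if (!inherits(prof, "try-error")) {
      readr::write_tsv(prof$profile,
                       file.path(config$out_dir, "positional_profile_S.tsv"))
      res$profile_S_control_band <- as.list(prof$control_band)
    }
    summary$stages$windows <- c(list(seed = sseed), res)
  }

  # --- motif classification -------------------------------------------------
  if ("classify" %in% config$stages) {
    subsets <- pser_window_subsets(proteins, sites, config$halfwidth)
    if (length(subsets) > 0) {
      cf <- class_frequencies(subsets)
      readr::write_tsv(cf, file.path(config$out_dir, "class_frequencies.tsv"))
      summary$stages$classify <- list(
        subsets = lapply(subsets, length),
        frequencies = split(stats::setNames(cf$frequency, cf$class),
                            cf$subset))
    }
    if (!is.null(patterns)) {
      tal <- tally_determinant_positions(patterns, config$halfwidth)
      readr::write_tsv(tal,
                       file.path(config$out_dir, "determinant_positions.tsv"))
    }
  }

  # --- enrichment -----------------------------------------------------------
  if ("enrich" %in% config$stages && !is.null(annotations)) {
    test <- intersect(meto_acc, phospho_acc)
    if (length(test) >= 1 && length(phospho_acc) >= length(test)) {
      enr <- hypergeom_enrichment(test, phospho_acc, annotations)
      readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
      summary$stages$enrich <- list(
        n_terms = nrow(enr),
        n_significant = sum(enr$p_bonferroni < 0.05))
    }
  } else if ("enrich" %in% config$stages) {
    summary$stages$enrich <- list(skipped = "no annotations supplied")
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
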