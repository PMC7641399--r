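# One-call orchestration of the full analysis.

#' Run the full HLA population analysis
#'
#' Drives every stage of the package from one configuration: diversity
#' summaries, HWP exact tests, Ewens-Watterson and Tajima's D neutrality
#' tests, allele classification with per-population and regional category
#' sums, pairwise F_ST with regional aggregation and Z_ST
#' standardization, and EM-based ASH summaries. Stages whose inputs are
#' absent (e.g. no sequence map, no microsatellite panel) are skipped
#' with a logged notice; schema violations fail hard. Every stochastic
#' stage draws its seed from the configured master seed, so a repeated
#' run with the same configuration is identical.
#'
#' @param config a list, or path to a YAML file, with (all optional)
#'   entries: `simulate` (logical or a list of [sim_params()] overrides —
#'   generate the inputs synthetically), `inputs` (paths: `cohort`,
#'   `region_map`, `msat`, `reference`, `sequences` as a named
#'   locus-to-FASTA list), `exclude` (populations excluded from regional
#'   summaries; default `"Ache"`), `seed` (master seed), `hwp_mc_steps`,
#'   `tajima_sims`, `em_restarts`.
#' @param out_dir optional directory; when given, every result table is
#'   written there as TSV together with a JSON run log.
#' @return a named list of result tibbles (invisibly when `out_dir` is
#'   given): `diversity`, `msat_diversity`, `hwp`, `hwp_residuals`,
#'   `ewens_watterson`, `tajima`, `classification`, `category_sums`,
#'   `region_category_means`, `correlations`, `fst_pairs`,
#'   `fst_region_means`, `zst`, `zst_region`, `ash_by_locus`,
#'   `ash_by_stratum`, plus `log`.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  exclude <- config$exclude %||% "Ache"
  seed <- config$seed %||% 1L
  seeds <- derive_seeds(seed, 5L)
  log <- list(seed = seed, started = format(Sys.time()), stages = list())
  note <- function(stage, msg, t0) {
    log$stages[[stage]] <<- list(note = msg, seconds = round(as.numeric(Sys.time()) - t0, 2))
    message("[", stage, "] ", msg)
  }

  # --- inputs ---
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    overrides <- if (is.list(config$simulate)) config$simulate else list()
    overrides$seed <- overrides$seed %||% seeds[[1]]
    params <- do.call(sim_params, overrides)
    sim <- sim_cohort(params)
    cohort <- sim$cohort
    regions <- sim$regions
    msat <- sim$msat
    reference <- sim$reference
    seqmap <- sim$sequences
    note("inputs", "synthetic cohort generated", t0)
  } else {
    inp <- config$inputs
    if (is.null(inp$cohort)) abort("Config needs either 'simulate' or 'inputs$cohort'.")
    regions <- if (!is.null(inp$region_map)) read_region_map(inp$region_map) else NULL
    cohort <- read_cohort(inp$cohort, region_map = regions)
    msat <- if (!is.null(inp$msat)) read_msat_panel(inp$msat) else NULL
    reference <- if (!is.null(inp$reference)) read_reference_panel(inp$reference) else NULL
    seqmap <- if (!is.null(inp$sequences)) {
      dplyr::bind_rows(purrr::imap(inp$sequences, function(p, lc) {
        read_sequence_map(p, lc)
      }))
    } else {
      NULL
    }
    note("inputs", "inputs read from files", t0)
  }

  out <- list()
  freqs <- allele_frequencies(cohort)

  # --- diversity ---
  t0 <- as.numeric(Sys.time())
  out$diversity <- heterozygosity(freqs)
  out$allele_counts <- cohort_allele_count(cohort)
  if (!is.null(msat)) out$msat_diversity <- msat_heterozygosity(msat)
  note("diversity", "heterozygosity and allele counts computed", t0)

  # --- HWP ---
  t0 <- as.numeric(Sys.time())
  hw <- hwp_test(cohort, mc_steps = config$hwp_mc_steps %||% 5000,
                 seed = seeds[[2]])
  out$hwp <- hw[, setdiff(names(hw), "result")]
  out$hwp_residuals <- dplyr::bind_rows(purrr::map2(
    hw$result, seq_len(nrow(hw)),
    function(r, i) {
      dplyr::mutate(genotype_residuals(r),
                    population = hw$population[i], locus = hw$locus[i],
                    .before = 1)
    }
  ))
  note("hwp", paste0(sum(hw$significant), " of ", nrow(hw),
                     " tests significant at 0.05"), t0)

  # --- neutrality ---
  t0 <- as.numeric(Sys.time())
  out$ewens_watterson <- ewens_watterson_test(cohort, seed = seeds[[3]])
  note("ewens_watterson", "Ewens-Watterson tests computed", t0)
  t0 <- as.numeric(Sys.time())
  if (!is.null(seqmap)) {
    out$tajima <- tajima_test(cohort, seqmap,
                              loci = intersect(c("A", "B", "C"), unique(seqmap$locus)),
                              n_sims = config$tajima_sims %||% 2000,
                              seed = seeds[[4]])
    note("tajima", "Tajima's D computed on sequence-recoded samples", t0)
  } else {
    note("tajima", "skipped: no sequence map supplied", t0)
  }

  # --- classification ---
  t0 <- as.numeric(Sys.time())
  if (!is.null(reference)) {
    native_pops <- if (!is.null(regions)) {
      regions$population[regions$region %in% native_regions()]
    } else {
      unique(cohort$population)
    }
    native_cohort <- dplyr::filter(cohort, .data$population %in% native_pops)
    cls <- suppressWarnings(
      classify_alleles(native_cohort, reference, regions = regions)
    )
    out$classification <- cls
    native_freqs <- allele_frequencies(native_cohort)
    out$category_sums <- category_frequency_sums(native_freqs, cls)
    if (!is.null(regions)) {
      out$region_category_means <- region_category_means(
        out$category_sums, regions, exclude = exclude
      )
    }
    note("classify", paste0(sum(cls$category == "endemic"), " endemic, ",
                            sum(cls$category == "LFD"), " LFD alleles"), t0)
  } else {
    note("classify", "skipped: no reference panel supplied", t0)
  }

  # --- correlations with the neutral background ---
  t0 <- as.numeric(Sys.time())
  if (!is.null(msat)) {
    mh <- out$msat_diversity
    hh <- dplyr::summarise(
      dplyr::group_by(out$diversity, .data$population),
      H_hla = mean(.data$H), .groups = "drop"
    )
    both <- dplyr::inner_join(hh, mh, by = "population")
    per_locus <- dplyr::group_modify(
      dplyr::group_by(out$diversity, .data$locus),
      function(g, key) {
        d <- dplyr::inner_join(g, mh, by = "population")
        population_level_correlation(d$H, d$H_msat)
      }
    )
    overall <- dplyr::mutate(population_level_correlation(both$H_hla, both$H_msat),
                             locus = "mean_HLA", .before = 1)
    out$correlations <- dplyr::bind_rows(dplyr::ungroup(per_locus), overall)
    if (!is.null(out$category_sums)) {
      out$category_correlations <- category_msat_correlation(
        out$category_sums, mh, exclude = exclude
      )
    }
    if (!is.null(regions)) {
      out$regional_contrasts <- tryCatch(
        regional_contrasts(setNames(mh[, c("population", "H_msat")],
                                    c("population", "H")),
                           regions, exclude = exclude),
        error = function(e) NULL
      )
      zyg <- individual_zygosity(cohort, msat)
      out$individual_association <- individual_level_association(zyg)
      out$class_trend <- suppressWarnings(homozygosity_class_trend(zyg, regions))
    }
    note("correlations", "HLA vs microsatellite comparisons computed", t0)
  } else {
    note("correlations", "skipped: no microsatellite panel supplied", t0)
  }

  # --- differentiation ---
  t0 <- as.numeric(Sys.time())
  out$fst_pairs <- pairwise_fst(cohort)
  if (!is.null(regions)) {
    out$fst_region_means <- region_summary(out$fst_pairs, regions,
                                           exclude = exclude)
  }
  if (!is.null(msat)) {
    msat_fst <- msat_pairwise_fst(msat)
    out$zst <- zst(out$fst_pairs, msat_fst)
    if (!is.null(regions)) {
      out$zst_region <- zst_region_summary(out$zst, regions, exclude = exclude)
      msat_region <- region_summary(
        dplyr::mutate(
          dplyr::summarise(dplyr::group_by(msat_fst, .data$pop1, .data$pop2),
                           fst = mean(.data$fst), .groups = "drop"),
          locus = "mean_msat"
        ),
        regions, exclude = exclude
      )
      out$fst_region_means <- dplyr::bind_rows(
        out$fst_region_means,
        dplyr::filter(msat_region, .data$locus == "mean_msat")
      )
    }
  }
  note("fst", "pairwise AMOVA F_ST and Z_ST computed", t0)

  # --- haplotypes / ASH ---
  t0 <- as.numeric(Sys.time())
  if (!is.null(out$classification)) {
    ashres <- ash_by_category(
      cohort, out$classification,
      em_args = list(restarts = config$em_restarts %||% 2),
      seed = seeds[[5]]
    )
    out$ash_alleles <- ashres$alleles
    out$ash_by_locus <- ashres$by_locus
    out$ash_by_stratum <- ashres$by_stratum
    note("ash", "EM haplotypes and ASH summaries computed", t0)
  } else {
    note("ash", "skipped: classification unavailable", t0)
  }

  log$finished <- format(Sys.time())
  out$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "log")) {
      if (is.data.frame(out[[nm]])) {
        readr::write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         progress = FALSE)
      }
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
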