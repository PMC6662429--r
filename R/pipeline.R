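# Orchestration: marker QC -> diversity -> F_ST -> spatial -> clusters ->
# hierarchical AMOVA -> Mantel -> Nm / Ne, with per-stage seeds derived from
# one master seed so that disabling a stage never shifts another's stream.

#' Pipeline configuration
#'
#' Defaults are the published analysis settings: 5 m thinning step, 95
#' envelope simulations, 16,000 permutations for F_IS / F_ST, 10,000 for the
#' hierarchical AMOVA and Mantel tests, a 0.20 null-allele exclusion
#' threshold, and pcrit 0.05 for the Ne estimators. All are overridable.
#'
#' @param study A `sim_study`, or `NULL` to read from files.
#' @param genotypes,coordinates,design File paths (Genepop, CSV, CSV) used
#'   when `study` is `NULL`.
#' @param stages Character vector of stages to run, a subset of the default.
#' @param r_max Named list of per-site maximum K distances (metres); `NULL`
#'   uses a quarter of the shorter window side.
#' @param envelope_nsim CSR simulations per envelope.
#' @param step Edge-thinning increment (metres).
#' @param td_radii Named list of per-site cluster radii (metres); `NULL`
#'   takes the smallest detected threshold distance per site.
#' @param perm_fis,perm_fst,perm_amova,perm_mantel Permutation counts.
#' @param null_threshold Null-allele exclusion threshold.
#' @param pcrit Minimum allele frequency for the Ne estimators.
#' @param seed Master seed.
#' @param out_dir If not `NULL`, tables are written there as CSV plus a JSON
#'   manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, genotypes = NULL, coordinates = NULL,
                            design = NULL,
                            stages = c("null_alleles", "diversity", "fst",
                                       "spatial", "thinning", "amova",
                                       "mantel", "geneflow", "ne"),
                            r_max = NULL, envelope_nsim = 95, step = 5,
                            td_radii = NULL, perm_fis = 16000,
                            perm_fst = 16000, perm_amova = 10000,
                            perm_mantel = 10000, null_threshold = 0.20,
                            pcrit = 0.05, seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_inputs <- function(config) {
  if (!is.null(config$study)) {
    list(panel = config$study$panel, patterns = config$study$patterns,
         design = config$study$design)
  } else {
    assert_that(!is.null(config$genotypes), "no genotypes given")
    panel <- read_genepop(config$genotypes)
    design <- if (!is.null(config$design)) read_design(config$design)
    if (!is.null(design)) panel <- apply_design(panel, design)
    patterns <- NULL
    if (!is.null(config$coordinates)) {
      coords <- read_coordinates(config$coordinates)
      sites <- unique(panel$site)
      sites <- sites[!is.na(sites)]
      patterns <- lapply(sites, function(s) {
        nests <- unique(panel$nest[panel$site == s])
        pp(pp_coords(coords)[coords$id %in% nests, ])
      }) |> setNames(sites)
    }
    list(panel = panel, patterns = patterns, design = design)
  }
}

run_stage <- function(name, manifest, params, code) {
  res <- tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  list(result = res,
       manifest = c(manifest, setNames(list(params), name)))
}

#' Run the full three-scale philopatry analysis
#'
#' Executes, in order: null-allele screen and locus filter, per-population
#' diversity (heterozygosity, exact HWE, F_IS), pairwise F_ST, Ripley's K
#' with CSR envelopes per site, edge thinning with plateau detection,
#' cluster assignment at the chosen threshold distances, four-level
#' hierarchical AMOVA per site, Mantel isolation-by-distance tests (all
#' hatchlings and one per nest), private-allele Nm, and the three Ne
#' estimators. Any stage failure halts with the stage name; completed
#' outputs are kept in the returned bundle.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `report_bundle` with one entry per completed
#'   stage plus a `manifest` recording parameters and seeds.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  inp <- load_inputs(config)
  panel <- inp$panel
  patterns <- inp$patterns
  seed <- config$seed
  bundle <- list()
  manifest <- list(master_seed = seed)
  st <- function(s) s %in% config$stages

  if (st("null_alleles")) {
    r <- run_stage("null_alleles", manifest,
                   list(threshold = config$null_threshold), {
      est <- null_allele_estimate(panel)
      panel2 <- filter_loci(panel, est, threshold = config$null_threshold)
      list(estimates = est, dropped = attr(panel2, "dropped_loci"),
           panel = panel2)
    })
    manifest <- r$manifest
    bundle$null_alleles <- r$result$estimates |>
      mutate(dropped = .data$locus %in% r$result$dropped)
    panel <- r$result$panel
  }
  if (st("diversity")) {
    r <- run_stage("diversity", manifest,
                   list(perm_fis = config$perm_fis,
                        seed = derive_seed(seed, "diversity")), {
      div <- heterozygosity(panel) |>
        left_join(hwe_exact(panel, reps = 2000,
                            seed = derive_seed(seed, "hwe")),
                  by = c("population", "locus", "n"))
      fis <- fis_weir_cockerham(panel, nperm = config$perm_fis,
                                seed = derive_seed(seed, "fis"))
      list(diversity = div, fis = fis)
    })
    manifest <- r$manifest
    bundle$diversity <- r$result$diversity
    bundle$fis <- r$result$fis
  }
  if (st("fst")) {
    r <- run_stage("fst", manifest,
                   list(permutations = config$perm_fst,
                        seed = derive_seed(seed, "fst")), {
      pairwise_fst(panel, nperm = config$perm_fst,
                   seed = derive_seed(seed, "fst"))
    })
    manifest <- r$manifest
    bundle$fst <- r$result
  }
  if (st("spatial")) {
    r <- run_stage("spatial", manifest,
                   list(nsim = config$envelope_nsim,
                        seed = derive_seed(seed, "spatial")), {
      assert_that(!is.null(patterns), "no nest coordinates available")
      lapply(names(patterns), function(s) {
        env <- csr_envelope(patterns[[s]],
                            r_max = config$r_max[[s]] %||% NULL,
                            nsim = config$envelope_nsim,
                            seed = derive_seed(seed, paste0("env_", s)))
        classify_dispersion(env)
      }) |> setNames(names(patterns))
    })
    manifest <- r$manifest
    bundle$spatial <- r$result
  }
  if (st("thinning")) {
    r <- run_stage("thinning", manifest, list(step = config$step), {
      assert_that(!is.null(patterns), "no nest coordinates available")
      profs <- lapply(patterns, edge_thinning, step = config$step)
      plats <- lapply(profs, detect_plateaus)
      list(profiles = profs, plateaus = plats)
    })
    manifest <- r$manifest
    bundle$thinning <- r$result$profiles
    bundle$plateaus <- r$result$plateaus
  }
  if (st("amova")) {
    r <- run_stage("amova", manifest,
                   list(permutations = config$perm_amova,
                        seed = derive_seed(seed, "amova")), {
      assert_that(!is.null(patterns), "no nest coordinates available")
      lapply(names(patterns), function(s) {
        radius <- config$td_radii[[s]]
        if (is.null(radius)) {
          plats <- detect_plateaus(edge_thinning(patterns[[s]],
                                                 step = config$step))
          radius <- if (nrow(plats) > 0) min(plats$td) else config$step * 4
        }
        asg <- assign_clusters(patterns[[s]], radius)
        sub <- set_clusters(panel |> filter(.data$site == s), asg)
        fit <- hierarchical_amova(sub, nperm = config$perm_amova,
                                  seed = derive_seed(seed, paste0("amova_", s)))
        list(site = s, radius = radius, fit = fit)
      }) |> setNames(names(patterns))
    })
    manifest <- r$manifest
    bundle$amova <- r$result
  }
  if (st("mantel")) {
    r <- run_stage("mantel", manifest,
                   list(permutations = config$perm_mantel,
                        seed = derive_seed(seed, "mantel")), {
      assert_that(!is.null(patterns), "no nest coordinates available")
      runs <- list()
      for (s in names(patterns)) {
        sub <- panel |> filter(.data$site == s)
        runs[[paste0(s, "_all")]] <-
          ibd_test(sub, patterns[[s]], nperm = config$perm_mantel,
                   seed = derive_seed(seed, paste0("mantel_", s)))
        runs[[paste0(s, "_one_per_nest")]] <-
          ibd_test(one_per_nest(sub), patterns[[s]],
                   nperm = config$perm_mantel,
                   seed = derive_seed(seed, paste0("mantel1_", s)))
      }
      bind_rows(runs, .id = "analysis")
    })
    manifest <- r$manifest
    bundle$mantel <- r$result
  }
  if (st("geneflow")) {
    r <- run_stage("geneflow", manifest, list(), {
      suppressMessages(private_allele_nm(panel, by = "population"))
    })
    manifest <- r$manifest
    bundle$nm <- r$result
  }
  if (st("ne")) {
    r <- run_stage("ne", manifest, list(pcrit = config$pcrit), {
      pops <- unique(panel$population)
      lapply(pops, function(p) {
        ne_estimates(panel |> filter(.data$population == p),
                     pcrit = config$pcrit) |>
          mutate(population = p, .before = 1)
      }) |> bind_rows()
    })
    manifest <- r$manifest
    bundle$ne <- r$result
  }
  bundle$manifest <- manifest
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    x <- as.data.frame(x)
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) ifelse(is.infinite(v), "inf", v))
    write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  if (!is.null(bundle$null_alleles)) wr(bundle$null_alleles, "null_alleles")
  if (!is.null(bundle$diversity)) wr(bundle$diversity, "diversity")
  if (!is.null(bundle$fis)) wr(bundle$fis, "fis")
  if (!is.null(bundle$fst)) wr(bundle$fst, "fst")
  if (!is.null(bundle$spatial)) {
    for (s in names(bundle$spatial)) wr(bundle$spatial[[s]],
                                        paste0("spatial_", s))
  }
  if (!is.null(bundle$thinning)) {
    for (s in names(bundle$thinning)) {
      wr(bundle$thinning[[s]], paste0("thinning_", s))
      wr(bundle$plateaus[[s]], paste0("plateaus_", s))
    }
  }
  if (!is.null(bundle$amova)) {
    for (s in names(bundle$amova)) {
      wr(amova_report(bundle$amova[[s]]$fit), paste0("amova_", s))
    }
  }
  if (!is.null(bundle$mantel)) wr(bundle$mantel, "mantel")
  if (!is.null(bundle$nm)) wr(bundle$nm, "nm")
  if (!is.null(bundle$ne)) wr(bundle$ne, "ne")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Human-readable summary of a pipeline run
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return A character vector of markdown lines (also printed with
#'   `cat(make_report(b), sep = "\n")`).
#' @export
make_report <- function(bundle) {
  out <- c("# Philopatry analysis report", "")
  if (!is.null(bundle$spatial)) {
    out <- c(out, "## Spatial pattern of nests")
    for (s in names(bundle$spatial)) {
      cl <- bundle$spatial[[s]]
      frac <- mean(cl$dispersion == "clustered")
      verdict <- if (any(cl$dispersion == "clustered")) "clustered"
        else if (any(cl$dispersion == "overdispersed")) "overdispersed"
        else "random"
      out <- c(out, sprintf(
        "- %s: %s (observed K outside the CSR envelope at %.0f%% of distances)",
        s, verdict, 100 * frac))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$amova)) {
    out <- c(out, "## Hierarchical AMOVA (clusters / nests / individuals)")
    for (s in names(bundle$amova)) {
      f <- bundle$amova[[s]]$fit$statistics
      out <- c(out, sprintf("- %s (radius %g m):", s,
                            bundle$amova[[s]]$radius))
      for (i in seq_len(nrow(f))) {
        out <- c(out, sprintf("    - %s = %.3f (p = %.4f)", f$statistic[i],
                              f$estimate[i], f$p[i]))
      }
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$mantel)) {
    out <- c(out, "## Isolation by distance (Mantel)")
    m <- bundle$mantel
    for (i in seq_len(nrow(m))) {
      out <- c(out, sprintf("- %s: R = %.3f, R^2 = %.3f, p = %.4f",
                            m$analysis[i], m$r[i], m$r2[i], m$p[i]))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$fst)) {
    out <- c(out, "## Pairwise F_ST")
    f <- bundle$fst
    for (i in seq_len(nrow(f))) {
      out <- c(out, sprintf("- %s vs %s: F_ST = %.3f (p = %.4f)",
                            f$group1[i], f$group2[i], f$fst[i], f$p[i]))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$nm)) {
    out <- c(out, sprintf("Gene flow (private alleles): Nm = %.2f", bundle$nm$nm),
             "")
  }
  if (!is.null(bundle$ne)) {
    out <- c(out, "## Effective population size")
    ne <- bundle$ne
    for (i in seq_len(nrow(ne))) {
      out <- c(out, sprintf("- %s, %s: Ne = %s [%s, %s]", ne$population[i],
                            ne$method[i], format(ne$ne[i], digits = 3),
                            format(ne$ci_lo[i], digits = 3),
                            format(ne$ci_hi[i], digits = 3)))
    }
  }
  out
}
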