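# Synthetic studies with known truth: clustered nest point patterns inside
# rectangular windows, and family-structured microsatellite genotypes in
# which every clutch is a full-sib family.  The philopatry strength phi is
# the probability that a nest's mother is drawn from the matriline attached
# to the nest's latent spatial cluster (related females nest together) rather
# than from the site-wide pool; phi = 0 is the no-philopatry null.

#' Simulation configuration
#'
#' Defaults emulate the field system the package targets: two nesting sites
#' of the published window sizes roughly 1.5 km apart, about two dozen
#' genotyped nests per site arising from a Thomas cluster process, clutches
#' of full siblings with mean size 12.5 clipped to 2-23 eggs, 13
#' microsatellite loci, and moderate between-site divergence (F around
#' 0.02).
#'
#' @param sites Named list of per-site settings; each entry has `window`
#'   (`c(xmin, xmax, ymin, ymax)` in metres) and a point-process spec
#'   (`process` = `"thomas"` or `"csr"` with `kappa`, `mu`, `sigma` or
#'   `lambda`).
#' @param n_loci Number of microsatellite loci.
#' @param alleles_per_locus Alleles segregating per locus.
#' @param divergence_f Balding-Nichols divergence F between sites.
#' @param clutch_mean,clutch_range Clutch-size law: Poisson mean, clipped to
#'   the range.
#' @param philopatry_phi Probability in `[0, 1]` that a nesting mother comes
#'   from her cluster's matriline rather than the site-wide pool.
#' @param n_matrilines Founder matrilines per site.
#' @param missing_rate Fraction of genotypes masked as missing, uniformly at
#'   random.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    sites = list(
      TIE = list(window = c(0, 454, 0, 695), process = "thomas",
                 kappa = 6 / (454 * 695), mu = 4, sigma = 15),
      MAL = list(window = c(1600, 1770, 0, 476), process = "thomas",
                 kappa = 6 / (170 * 476), mu = 4, sigma = 15)
    ),
    n_loci = 13, alleles_per_locus = 8, divergence_f = 0.02,
    clutch_mean = 12.5, clutch_range = c(2, 23),
    philopatry_phi = 0, n_matrilines = 20, missing_rate = 0.02) {
  assert_that(philopatry_phi >= 0 && philopatry_phi <= 1,
              "philopatry_phi must be in [0, 1]")
  assert_that(divergence_f >= 0 && divergence_f < 1,
              "divergence_f must be in [0, 1)")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  assert_that(clutch_range[1] >= 1 && clutch_range[2] >= clutch_range[1],
              "invalid clutch_range")
  structure(list(sites = sites, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 divergence_f = divergence_f, clutch_mean = clutch_mean,
                 clutch_range = clutch_range,
                 philopatry_phi = philopatry_phi,
                 n_matrilines = n_matrilines, missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate a nest point pattern
#'
#' CSR draws a Poisson(lambda * area) number of uniform points. The Thomas
#' process draws Poisson(kappa * area) parent centres uniformly, Poisson(mu)
#' offspring per parent, displaces each isotropically by Gaussian sigma, and
#' keeps points inside the window. The latent parent index of each point is
#' kept in the `"parent"` attribute (the true cluster memberships).
#'
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)` in metres.
#' @param process `"thomas"` or `"csr"`.
#' @param lambda CSR intensity (points per square metre).
#' @param kappa,mu,sigma Thomas parent intensity, mean offspring per parent,
#'   Gaussian displacement sd (metres).
#' @param seed RNG seed.
#' @param prefix Id prefix for the points.
#' @return A `ppattern`; attribute `"parent"` holds the latent cluster index
#'   per point (all 1 for CSR).
#' @export
simulate_points <- function(window, process = c("thomas", "csr"),
                            lambda = NULL, kappa = NULL, mu = NULL,
                            sigma = NULL, seed = NULL, prefix = "N") {
  process <- match.arg(process)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  with_seed(seed, {
    if (process == "csr") {
      assert_that(!is.null(lambda) && lambda * area > 0,
                  "expected point count is zero")
      n <- rpois(1, lambda * area)
      xy <- tibble(id = paste0(prefix, seq_len(n)),
                   x = runif(n, window[1], window[2]),
                   y = runif(n, window[3], window[4]))
      parent <- rep(1L, n)
    } else {
      assert_that(!is.null(kappa) && !is.null(mu) && !is.null(sigma) &&
                    kappa * area > 0, "expected parent count is zero")
      n_par <- max(1L, rpois(1, kappa * area))
      px <- runif(n_par, window[1], window[2])
      py <- runif(n_par, window[3], window[4])
      n_off <- rpois(n_par, mu)
      parent <- rep(seq_len(n_par), n_off)
      x <- px[parent] + stats::rnorm(sum(n_off), 0, sigma)
      y <- py[parent] + stats::rnorm(sum(n_off), 0, sigma)
      keep <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
      x <- x[keep]; y <- y[keep]; parent <- parent[keep]
      xy <- tibble(id = paste0(prefix, seq_along(x)), x = x, y = y)
    }
    out <- pp(xy, window = window)
    attr(out, "parent") <- parent
    out
  })
}

#' Simulate ancestral and per-site allele frequencies
#'
#' Ancestral frequencies are Dirichlet-uniform per locus; each site draws
#' its own frequencies from the Balding-Nichols model, a Dirichlet with
#' concentration `ancestral * (1 - F) / F`, so that the expected
#' Weir-Cockerham divergence between sites is F. `F = 0` copies the
#' ancestral frequencies exactly.
#'
#' @param config A `sim_config`.
#' @param seed RNG seed.
#' @param site_names Names of the demes (default from `config$sites`).
#' @return A list with `ancestral` (loci x alleles matrix) and `sites`
#'   (named list of matrices).
#' @export
simulate_allele_frequencies <- function(config, seed = NULL,
                                        site_names = names(config$sites)) {
  L <- config$n_loci; A <- config$alleles_per_locus
  assert_that(A >= 2, "need at least 2 alleles per locus")
  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  with_seed(seed, {
    anc <- t(vapply(seq_len(L), function(i) rdirichlet(rep(1, A)),
                    numeric(A)))
    f <- config$divergence_f
    sites <- lapply(site_names, function(s) {
      if (f == 0) return(anc)
      t(vapply(seq_len(L), function(i) rdirichlet(anc[i, ] * (1 - f) / f),
               numeric(A)))
    })
    names(sites) <- site_names
    list(ancestral = anc, sites = sites)
  })
}

# Mendelian cross of two diploid genotypes (L x 2 matrices of allele codes).
mendel_cross <- function(mom, dad) {
  L <- nrow(mom)
  cbind(mom[cbind(seq_len(L), sample(1:2, L, replace = TRUE))],
        dad[cbind(seq_len(L), sample(1:2, L, replace = TRUE))])
}

random_genotype <- function(freq_mat) {
  L <- nrow(freq_mat)
  g <- vapply(seq_len(L), function(i) {
    sample.int(ncol(freq_mat), 2, replace = TRUE, prob = freq_mat[i, ])
  }, integer(2))
  t(g) + 100L  # allele codes 101, 102, ... (3-digit Genepop codes)
}

#' Simulate family-structured genotypes over nest point patterns
#'
#' Builds `n_matrilines` founder pairs per site; their daughters form the
#' pool of nesting females. Every nest receives one mother -- with
#' probability `philopatry_phi` from the matriline mapped to the nest's
#' latent spatial cluster, otherwise from the site-wide pool -- and one
#' site-wide father, and a clutch of full siblings by Mendelian draws
#' (Poisson(`clutch_mean`) clipped to `clutch_range`). Genotypes are masked
#' missing at `missing_rate`.
#'
#' @param config A `sim_config`.
#' @param freqs Frequencies from [simulate_allele_frequencies()].
#' @param patterns Named list of `ppattern`s, one per site (ids are nest
#'   labels; the `"parent"` attribute, if present, supplies latent
#'   clusters).
#' @param seed RNG seed.
#' @return A list of class `sim_study`: `panel` (genotype tibble of all
#'   hatchlings), `patterns`, `design`, and `truth` (generator parameters,
#'   parental genotypes, and the latent parentage of every hatchling).
#' @export
simulate_families <- function(config, freqs, patterns, seed = NULL) {
  loci_names <- sprintf("L%02d", seq_len(config$n_loci))
  with_seed(seed, {
    panels <- list()
    truth_parents <- list()
    designs <- list()
    for (s in names(patterns)) {
      patt <- patterns[[s]]
      n_nest <- nrow(patt)
      if (n_nest == 0) next
      fm <- freqs$sites[[s]]
      latent <- attr(patt, "parent") %||% rep(1L, n_nest)
      n_cl <- length(unique(latent))
      if (config$philopatry_phi == 1 && config$n_matrilines < n_cl) {
        abort(sprintf(
          "philopatry_phi = 1 needs at least as many matrilines (%d) as latent clusters (%d)",
          config$n_matrilines, n_cl))
      }
      # founder pairs and their daughters (the nesting females)
      daughters_per <- max(2L, ceiling(2 * n_nest / config$n_matrilines))
      matri <- lapply(seq_len(config$n_matrilines), function(m) {
        fm_mom <- random_genotype(fm)
        fm_dad <- random_genotype(fm)
        lapply(seq_len(daughters_per), function(d) mendel_cross(fm_mom, fm_dad))
      })
      cl_to_matri <- ((sort(unique(latent)) - 1L) %% config$n_matrilines) + 1L
      names(cl_to_matri) <- sort(unique(latent))
      rows <- list()
      parent_rec <- list()
      for (ni in seq_len(n_nest)) {
        nest_id <- paste0(s, "_", patt$id[ni])
        ml <- cl_to_matri[[as.character(latent[ni])]]
        philopatric <- runif(1) < config$philopatry_phi
        if (philopatric) {
          mom_matri <- ml
        } else {
          mom_matri <- sample.int(config$n_matrilines, 1)
        }
        mom <- matri[[mom_matri]][[sample.int(daughters_per, 1)]]
        dad <- random_genotype(fm)
        clutch <- min(max(rpois(1, config$clutch_mean),
                          config$clutch_range[1]), config$clutch_range[2])
        for (k in seq_len(clutch)) {
          child <- mendel_cross(mom, dad)
          rows[[length(rows) + 1L]] <- tibble(
            id = sprintf("%s_h%03d", nest_id, k),
            population = s, site = s, nest = nest_id, stage = "hatchling",
            locus = loci_names, a1 = pmin(child[, 1], child[, 2]),
            a2 = pmax(child[, 1], child[, 2])
          )
        }
        parent_rec[[nest_id]] <- list(
          mother = mom, father = dad, matriline = mom_matri,
          latent_cluster = paste0(s, "_K", latent[ni]),
          philopatric = philopatric, clutch = clutch
        )
      }
      panel <- bind_rows(rows)
      if (config$missing_rate > 0) {
        key <- paste(panel$id, panel$locus)
        ukey <- unique(key)
        mask <- ukey[runif(length(ukey)) < config$missing_rate]
        hit <- key %in% mask
        panel$a1[hit] <- NA_integer_
        panel$a2[hit] <- NA_integer_
      }
      panels[[s]] <- panel
      truth_parents[[s]] <- parent_rec
      designs[[s]] <- panel |>
        distinct(individual = .data$id, nest = .data$nest) |>
        mutate(cluster = vapply(.data$nest, function(nn)
          parent_rec[[nn]]$latent_cluster, character(1)),
          site = s, population = s)
    }
    panel <- bind_rows(panels)
    # prefix nest ids on the patterns so they match the design
    patterns <- lapply(names(patterns), function(s) {
      patt <- patterns[[s]]
      out <- pp(tibble(id = paste0(s, "_", patt$id), x = patt$x, y = patt$y),
                window = pp_window(patt))
      attr(out, "parent") <- attr(patt, "parent")
      out
    }) |> setNames(names(patterns))
    structure(list(
      panel = panel, patterns = patterns, design = bind_rows(designs),
      truth = list(config = unclass(config), parents = truth_parents,
                   loci = loci_names)
    ), class = "sim_study")
  })
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_points()], [simulate_allele_frequencies()] and
#' [simulate_families()] under one seed.
#'
#' @param config A `sim_config`.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A `sim_study` (see [simulate_families()]).
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  patterns <- lapply(names(config$sites), function(s) {
    sc <- config$sites[[s]]
    simulate_points(sc$window, process = sc$process, lambda = sc$lambda,
                    kappa = sc$kappa, mu = sc$mu, sigma = sc$sigma,
                    seed = if (!is.null(seed)) derive_seed(seed, paste0("pts_", s)),
                    prefix = "N")
  }) |> setNames(names(config$sites))
  freqs <- simulate_allele_frequencies(
    config, seed = if (!is.null(seed)) derive_seed(seed, "freqs"))
  study <- simulate_families(
    config, freqs, patterns,
    seed = if (!is.null(seed)) derive_seed(seed, "families"))
  study$truth$seed <- seed
  study$truth$freqs <- freqs
  study
}

#' Write a synthetic study to disk
#'
#' Emits `genotypes.gen` (Genepop), `coordinates.csv`, `design.csv` and
#' `truth.json` into `dir`.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genepop(study$panel, file.path(dir, "genotypes.gen"))
  coords <- bind_rows(lapply(study$patterns, pp_coords))
  write.csv(coords, file.path(dir, "coordinates.csv"), row.names = FALSE)
  write.csv(study$design, file.path(dir, "design.csv"), row.names = FALSE)
  truth <- study$truth
  truth$parents <- lapply(truth$parents, function(site_rec) {
    lapply(site_rec, function(p) {
      list(mother = as.vector(t(p$mother)), father = as.vector(t(p$father)),
           matriline = p$matriline, latent_cluster = p$latent_cluster,
           philopatric = p$philopatric, clutch = p$clutch)
    })
  })
  truth$freqs <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
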