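# Fixture builders and independent oracles used across the suite.

# ---- genotype fixture builders ---------------------------------------------

# genotype tibble from a list of n x 2 matrices (one per individual), all at
# the same loci
geno_from_inds <- function(ind_list, ids = NULL, population = "P",
                           nest = NA_character_, cluster = NULL,
                           loci = NULL) {
  L <- nrow(ind_list[[1]])
  loci <- loci %||% sprintf("L%02d", seq_len(L))
  ids <- ids %||% sprintf("i%03d", seq_along(ind_list))
  population <- rep_len(population, length(ind_list))
  nest <- rep_len(nest, length(ind_list))
  if (!is.null(cluster)) cluster <- rep_len(cluster, length(ind_list))
  dplyr::bind_rows(lapply(seq_along(ind_list), function(i) {
    m <- ind_list[[i]]
    out <- tibble::tibble(
      id = ids[i], population = population[i], site = population[i],
      nest = nest[i], stage = "hatchling", locus = loci,
      a1 = pmin(m[, 1], m[, 2]), a2 = pmax(m[, 1], m[, 2])
    )
    if (!is.null(cluster)) out$cluster <- cluster[i]
    out
  }))
}

rand_ind <- function(L = 10, A = 8, fm = NULL) {
  fm <- fm %||% matrix(1 / A, L, A)
  nestgen:::random_genotype(fm)
}

# full-sib families from n_pairs parent pairs, n_off offspring each
family_geno <- function(n_pairs, n_off, L = 15, A = 8, nest_prefix = "n") {
  fm <- matrix(1 / A, L, A)
  inds <- list(); nests <- character()
  for (f in seq_len(n_pairs)) {
    mom <- nestgen:::random_genotype(fm)
    dad <- nestgen:::random_genotype(fm)
    for (k in seq_len(n_off)) {
      inds[[length(inds) + 1L]] <- nestgen:::mendel_cross(mom, dad)
      nests <- c(nests, paste0(nest_prefix, f))
    }
  }
  geno_from_inds(inds, nest = nests)
}

unrelated_geno <- function(n, L = 15, A = 8) {
  geno_from_inds(lapply(seq_len(n), function(i) rand_ind(L, A)))
}

# ideal Wright-Fisher population (monoecious, selfing allowed) run to LD
# drift equilibrium, then one offspring cohort sampled
wf_cohort_geno <- function(Ne = 50, gens = 10, n = 50, L = 20, A = 8) {
  fm <- matrix(1 / A, L, A)
  pop <- lapply(seq_len(Ne), function(i) nestgen:::random_genotype(fm))
  for (g in seq_len(gens)) {
    pop <- lapply(seq_len(Ne), function(i) {
      pr <- sample(Ne, 2, replace = TRUE)
      nestgen:::mendel_cross(pop[[pr[1]]], pop[[pr[2]]])
    })
  }
  geno_from_inds(lapply(seq_len(n), function(k) {
    pr <- sample(Ne, 2, replace = TRUE)
    nestgen:::mendel_cross(pop[[pr[1]]], pop[[pr[2]]])
  }))
}

# two demes sampled from Balding-Nichols frequencies at divergence F
bn_two_demes <- function(f, n_per = 100, L = 20, A = 8) {
  cfg <- sim_config(divergence_f = f, n_loci = L, alleles_per_locus = A)
  fr <- simulate_allele_frequencies(cfg)
  dplyr::bind_rows(lapply(names(fr$sites)[1:2], function(s) {
    geno_from_inds(lapply(seq_len(n_per), function(i) rand_ind(fm = fr$sites[[s]])),
                   ids = sprintf("%s_%03d", s, seq_len(n_per)),
                   population = s)
  }))
}

uniform_points <- function(n, window = c(0, 1, 0, 1)) {
  pp(tibble::tibble(id = as.character(seq_len(n)),
                    x = runif(n, window[1], window[2]),
                    y = runif(n, window[3], window[4])), window = window)
}

# ---- independent oracles ----------------------------------------------------

# brute-force Ripley K, no correction
k_bruteforce <- function(pattern, r_grid) {
  xy <- cbind(pattern$x, pattern$y)
  n <- nrow(xy)
  area <- pp_area(pattern)
  d <- as.matrix(dist(xy))
  sapply(r_grid, function(r) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && d[i, j] <= r) cnt <- cnt + 1
    }
    area * cnt / (n * (n - 1))
  })
}

# BFS connected-component labelling of the threshold graph
bfs_components <- function(pattern, radius) {
  n <- nrow(pattern)
  d <- as.matrix(dist(cbind(pattern$x, pattern$y)))
  lab <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(d[v, ] <= radius & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# exact Hardy-Weinberg test by complete enumeration, biallelic locus
hwe_enum_biallelic <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  logp <- function(h) {
    hom1 <- (n1 - h) / 2
    hom2 <- (2 * n - n1 - h) / 2
    lfactorial(n) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) +
      h * log(2) + lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n)
  }
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  lp <- vapply(hs, logp, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[hs == n12]
  sum(pr[pr <= obs + 1e-12])
}

# brute-force four-level AMOVA from the explicit allele-copy distance matrix
# (identity distance); mean-square equations applied to sums of squares that
# are computed as (1/m) * sum of pairwise distances within each grouping.
amova_bruteforce <- function(geno) {
  dat <- geno[!is.na(geno$a1) & !is.na(geno$nest) & !is.na(geno$cluster), ]
  sig <- matrix(NA_real_, 0, 4)
  for (l in unique(dat$locus)) {
    ld <- dat[dat$locus == l, ]
    copies <- c(ld$a1, ld$a2)
    ind <- c(ld$id, ld$id)
    nest <- c(ld$nest, ld$nest)
    cl <- c(ld$cluster, ld$cluster)
    m <- length(copies)
    D <- outer(copies, copies, function(a, b) as.numeric(a != b))
    ss_of <- function(groups) {
      tot <- 0
      for (g in unique(groups)) {
        w <- which(groups == g)
        if (length(w) > 1) {
          sub <- D[w, w]
          tot <- tot + sum(sub[upper.tri(sub)]) / length(w)
        }
      }
      tot
    }
    ss_tot <- ss_of(rep(1, m))
    ss_wc <- ss_of(cl)
    ss_wn <- ss_of(nest)
    ss_wi <- ss_of(ind)
    N <- nrow(ld)
    P <- length(unique(ld$nest))
    G <- length(unique(ld$cluster))
    Ncop <- 2 * N
    n_p <- 2 * table(ld$nest)
    cl_of_nest <- ld$cluster[match(names(n_p), ld$nest)]
    N_g <- tapply(n_p, cl_of_nest, sum)
    A <- sum(n_p^2 / N_g[cl_of_nest])
    B <- sum(n_p^2) / Ncop
    C <- sum(N_g^2) / Ncop
    s4 <- ss_wi / N
    s3 <- if (N > P) ((ss_wn - ss_wi) / (N - P) - s4) / 2 else NA_real_
    s34 <- s4 + 2 * ifelse(is.na(s3), 0, s3)
    s2 <- if (P > G) {
      ((ss_wc - ss_wn) / (P - G) - s34) / ((Ncop - A) / (P - G))
    } else NA_real_
    s1 <- if (G > 1) {
      ((ss_tot - ss_wc) / (G - 1) - s34 -
         (A - B) / (G - 1) * ifelse(is.na(s2), 0, s2)) / ((Ncop - C) / (G - 1))
    } else NA_real_
    sig <- rbind(sig, c(s1, s2, s3, s4))
  }
  out <- colSums(sig, na.rm = TRUE)
  out[apply(sig, 2, function(v) all(is.na(v)))] <- NA_real_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
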