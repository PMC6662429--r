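# Canonical genotype table ("geno"): one row per individual x locus, columns
#   id, population, site, nest, stage, locus, a1, a2   (cluster optional)
# Allele codes are opaque positive integers; a missing genotype has both a1
# and a2 NA (half-calls are rejected at parse time).

#' Construct a genotype table
#'
#' Builds the long genotype tibble used by every analysis function: one row
#' per individual and locus, with the two allele codes in `a1`/`a2` and the
#' study-design labels carried alongside.
#'
#' @param id Character vector of individual identifiers (one per row).
#' @param locus Character vector of locus names.
#' @param a1,a2 Integer allele codes; both `NA` for a missing genotype.
#' @param population,site,nest,stage,cluster Optional design labels, recycled
#'   to the number of rows.
#' @return A tibble with class behaviour of a plain tibble; columns as above.
#' @export
#' @examples
#' geno_tbl(
#'   id = c("A", "A", "B", "B"),
#'   locus = c("L1", "L2", "L1", "L2"),
#'   a1 = c(101L, 204L, 101L, 202L), a2 = c(103L, 204L, 101L, 204L),
#'   population = "P1"
#' )
geno_tbl <- function(id, locus, a1, a2, population = NA_character_,
                     site = NA_character_, nest = NA_character_,
                     stage = NA_character_, cluster = NULL) {
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    abort(paste0("half-called genotypes (one allele missing) at rows: ",
                 paste(which(half), collapse = ", ")))
  }
  out <- tibble(
    id = as.character(id),
    population = as.character(population),
    site = as.character(site),
    nest = as.character(nest),
    stage = as.character(stage),
    locus = as.character(locus),
    a1 = as.integer(a1), a2 = as.integer(a2)
  )
  if (!is.null(cluster)) out$cluster <- as.character(cluster)
  bad <- !is.na(out$a1) & (out$a1 <= 0L | out$a2 <= 0L)
  if (any(bad)) abort("allele codes must be positive integers (0 means missing)")
  out
}

#' Loci of a genotype table, in original order
#'
#' @param geno A genotype tibble from [geno_tbl()] or a reader.
#' @return Character vector of locus names.
#' @export
geno_loci <- function(geno) {
  if (nrow(geno) > 0) unique(geno$locus) else attr(geno, "loci") %||% character()
}

#' Individuals of a genotype table, in original order
#' @inheritParams geno_loci
#' @return Character vector of individual ids.
#' @export
geno_inds <- function(geno) unique(geno$id)

#' Read a Genepop genotype file
#'
#' Parses the classic Genepop layout: a title line, locus names (one per line
#' or comma-separated), then `POP` blocks of `id , a1a2 a1a2 ...` rows with
#' fused fixed-width allele codes. All-zero codes (`000000`, `0000`) are
#' treated as missing genotypes, never as an allele `0`.
#'
#' @param path Path to the Genepop file.
#' @param allele_length Digits per allele in the fused code (2 or 3).
#' @param pop_names Optional character vector naming the `POP` blocks; the
#'   default labels them `pop_1`, `pop_2`, ...
#' @return A genotype tibble (see [geno_tbl()]); the `POP` blocks become the
#'   `population` label.
#' @export
read_genepop <- function(path, allele_length = 3, pop_names = NULL) {
  assert_that(allele_length %in% c(2, 3), "allele_length must be 2 or 3")
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  if (length(lines) < 2) abort("not a Genepop file: fewer than 2 lines")
  is_pop <- toupper(lines) == "POP"
  first_pop <- if (any(is_pop)) which(is_pop)[1] else length(lines) + 1L
  locus_lines <- lines[2:(first_pop - 1)]
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) abort("duplicated locus names in Genepop header")
  w <- as.integer(allele_length)

  rows <- list()
  pop_i <- 0L
  pop_lab <- NA_character_
  for (ln in seq_along(lines)) {
    if (ln < first_pop) next
    line <- lines[ln]
    if (!nzchar(line)) next
    if (toupper(line) == "POP") {
      pop_i <- pop_i + 1L
      pop_lab <- if (!is.null(pop_names)) pop_names[pop_i] else paste0("pop_", pop_i)
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2) {
      abort(sprintf("line %d: expected 'id , genotypes' with a comma", ln))
    }
    ind <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != length(loci)) {
      abort(sprintf("line %d: %d genotypes for %d loci", ln, length(gstr), length(loci)))
    }
    if (!all(grepl("^[0-9]+$", gstr)) || !all(nchar(gstr) == 2L * w)) {
      abort(sprintf("line %d: genotype codes must be %d digits (diploid, %d per allele)",
                    ln, 2L * w, w))
    }
    a1 <- as.integer(substr(gstr, 1L, w))
    a2 <- as.integer(substr(gstr, w + 1L, 2L * w))
    half <- xor(a1 == 0L, a2 == 0L)
    if (any(half)) {
      abort(sprintf("line %d: half-missing genotype at locus %s",
                    ln, loci[which(half)[1]]))
    }
    miss <- a1 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    rows[[length(rows) + 1L]] <- tibble(
      id = ind, population = pop_lab, locus = loci, a1 = a1, a2 = a2
    )
  }
  if (length(rows) == 0) {
    out <- geno_tbl(id = character(), locus = character(),
                    a1 = integer(), a2 = integer())
    attr(out, "loci") <- loci
    return(out)
  }
  out <- bind_rows(rows) |>
    mutate(site = NA_character_, nest = NA_character_, stage = NA_character_) |>
    select("id", "population", "site", "nest", "stage", "locus", "a1", "a2")
  attr(out, "loci") <- loci
  out
}

#' Write a genotype table as a Genepop file
#'
#' @inheritParams geno_loci
#' @param path Output file path.
#' @param allele_length Digits per allele in the fused code.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, allele_length = 3,
                          title = "nestgen export") {
  w <- as.integer(allele_length)
  loci <- geno_loci(geno)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = w, flag = "0")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  wide <- geno |>
    mutate(g = paste0(fmt(.data$a1), fmt(.data$a2))) |>
    select("id", "population", "locus", "g") |>
    pivot_wider(names_from = "locus", values_from = "g")
  pops <- unique(wide$population)
  for (p in pops) {
    writeLines("POP", con)
    blk <- wide[wide$population %in% p, , drop = FALSE]
    writeLines(paste0(blk$id, " , ",
                      apply(as.matrix(blk[, loci, drop = FALSE]), 1, paste,
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Read genotypes from the wide CSV dialect
#'
#' Expects columns `id, population, site, nest, stage` followed by two columns
#' per locus named `<locus>.a1` and `<locus>.a2`. Zero or empty allele cells
#' mean a missing genotype.
#'
#' @param path CSV path.
#' @return A genotype tibble.
#' @export
read_genotypes_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character")))
  meta <- intersect(c("id", "population", "site", "nest", "stage", "cluster"),
                    names(df))
  a1_cols <- grep("\\.a1$", names(df), value = TRUE)
  loci <- sub("\\.a1$", "", a1_cols)
  assert_that(length(loci) > 0, "no '<locus>.a1' columns found")
  assert_that(all(paste0(loci, ".a2") %in% names(df)),
              "every <locus>.a1 column needs a matching <locus>.a2")
  long <- df |>
    pivot_longer(cols = -dplyr::all_of(meta),
                 names_to = c("locus", ".value"),
                 names_pattern = "^(.*)\\.(a[12])$")
  long <- long |>
    mutate(a1 = suppressWarnings(as.integer(.data$a1)),
           a2 = suppressWarnings(as.integer(.data$a2)),
           a1 = ifelse(!is.na(.data$a1) & .data$a1 == 0L, NA_integer_, .data$a1),
           a2 = ifelse(!is.na(.data$a2) & .data$a2 == 0L, NA_integer_, .data$a2))
  for (col in setdiff(c("population", "site", "nest", "stage"), names(long))) {
    long[[col]] <- NA_character_
  }
  geno_tbl(id = long$id, locus = long$locus, a1 = long$a1, a2 = long$a2,
           population = long$population, site = long$site,
           nest = long$nest, stage = long$stage,
           cluster = long[["cluster"]])
}

#' Read a hierarchical study design table
#'
#' @param path CSV with columns `individual, nest, cluster, site, population`
#'   (`cluster` may be empty before spatial clusters are assigned).
#' @return A tibble with those columns.
#' @export
read_design <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"))
  need <- c("individual", "nest", "site", "population")
  assert_that(all(need %in% names(df)),
              paste("design CSV must have columns:", paste(need, collapse = ", ")))
  if (!"cluster" %in% names(df)) df$cluster <- NA_character_
  df[c("individual", "nest", "cluster", "site", "population")]
}

#' Attach or overwrite design labels on a genotype table
#'
#' @inheritParams geno_loci
#' @param design A design tibble from [read_design()].
#' @return The genotype tibble with `population`, `site`, `cluster`, `nest`
#'   taken from the design (matched on individual id).
#' @export
apply_design <- function(geno, design) {
  geno |>
    select(-dplyr::any_of(c("population", "site", "nest", "cluster"))) |>
    left_join(design |> rename(id = "individual"), by = "id") |>
    select(dplyr::any_of(c("id", "population", "site", "cluster", "nest",
                           "stage", "locus", "a1", "a2")))
}

#' Attach percolation cluster labels by nest
#'
#' @inheritParams geno_loci
#' @param assignment A tibble `id, cluster` from [assign_clusters()], where
#'   `id` is the nest identifier.
#' @return The genotype tibble with a `cluster` column.
#' @export
set_clusters <- function(geno, assignment) {
  geno |>
    select(-dplyr::any_of("cluster")) |>
    left_join(assignment |> rename(nest = "id"), by = "nest")
}

#' Subsample one hatchling per nest
#'
#' Repeated analyses in communal-nesting studies are rerun with a single
#' hatchling per nest to break up full-sib clutches. The original subsample
#' is rarely reported, so the rule here is deterministic: the first hatchling
#' by sorted id, or a seeded random draw.
#'
#' @inheritParams geno_loci
#' @param seed If `NULL` (default), take the alphabetically first hatchling
#'   id in each nest; otherwise draw one at random under this seed.
#' @return The genotype tibble restricted to one hatchling per nest (rows with
#'   no nest label are dropped).
#' @export
one_per_nest <- function(geno, seed = NULL) {
  hatch <- geno |> filter(!is.na(.data$nest))
  ids <- hatch |> distinct(.data$nest, .data$id) |> arrange(.data$nest, .data$id)
  keep <- with_seed(seed, {
    ids |>
      group_by(.data$nest) |>
      summarise(id = if (is.null(seed)) .data$id[1] else sample(.data$id, 1),
                .groups = "drop")
  })
  hatch |> semi_join(keep, by = c("nest", "id"))
}

#' Validate a study (genotypes, coordinates, design) for internal consistency
#'
#' Advisory checks report orphan nests (genotyped but with no coordinate),
#' unlabelled individuals, and loci typed in under half the individuals.
#' Violations of the design tree (a nest assigned to two clusters or sites, an
#' individual in two nests) are fatal.
#'
#' @inheritParams geno_loci
#' @param pattern Optional point pattern of nest coordinates ([pp()]).
#' @param design Optional design tibble ([read_design()]).
#' @return A tibble `check, item, message` of advisory findings (zero rows if
#'   the study is clean). Tree violations raise an error instead.
#' @export
validate_study <- function(geno, pattern = NULL, design = NULL) {
  findings <- list()
  tree <- if (!is.null(design)) {
    design |>
      rename(id = "individual") |>
      mutate(stage = NA_character_)
  } else {
    geno |> distinct(.data$id, .data$nest,
                     cluster = if ("cluster" %in% names(geno)) .data$cluster else NA_character_,
                     .data$site, .data$population)
  }
  # tree property: each unit has exactly one parent
  chk <- list(
    c("id", "nest"), c("nest", "cluster"), c("nest", "site"),
    c("cluster", "site"), c("site", "population")
  )
  for (pair in chk) {
    child <- pair[1]; parent <- pair[2]
    tab <- tree |>
      filter(!is.na(.data[[child]]), !is.na(.data[[parent]])) |>
      distinct(.data[[child]], .data[[parent]]) |>
      count(.data[[child]]) |>
      filter(.data$n > 1)
    if (nrow(tab) > 0) {
      abort(sprintf("design is not a tree: %s '%s' maps to %d different %ss",
                    child, tab[[child]][1], tab$n[1], parent))
    }
  }
  if (!is.null(pattern)) {
    nests <- unique(stats::na.omit(tree$nest))
    orphan <- setdiff(nests, pattern$id)
    for (o in orphan) {
      findings[[length(findings) + 1L]] <-
        tibble(check = "orphan_nest", item = o,
               message = "genotyped nest has no coordinate")
    }
  }
  unl <- tree |> filter(is.na(.data$population)) |> pull(.data$id)
  for (u in unique(unl)) {
    findings[[length(findings) + 1L]] <-
      tibble(check = "unlabeled_individual", item = u,
             message = "individual has no population label")
  }
  miss <- geno |>
    group_by(.data$locus) |>
    summarise(frac = mean(is.na(.data$a1)), .groups = "drop") |>
    filter(.data$frac > 0.5)
  for (i in seq_len(nrow(miss))) {
    findings[[length(findings) + 1L]] <-
      tibble(check = "high_missing_locus", item = miss$locus[i],
             message = sprintf("locus missing in %.0f%% of individuals",
                               100 * miss$frac[i]))
  }
  if (length(findings) == 0) {
    tibble(check = character(), item = character(), message = character())
  } else {
    bind_rows(findings)
  }
}
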