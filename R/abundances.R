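#' Validate (and normalise) a relative-abundance table
#'
#' An abundance table is a tibble with a `species` column (unique labels) and
#' a `p` column of strictly positive relative abundances summing to one. This
#' helper checks those invariants and renormalises `p` so the sum is exactly
#' one; species with zero abundance are dropped with a warning because the
#' sequential-sampling model requires every modelled species to be observable.
#'
#' @param x A data frame with columns `species` and `p` (or `abundance`).
#' @return A tibble with columns `species` (character) and `p` (double).
#' @export
#' @examples
#' as_abundances(data.frame(species = c("a", "b"), p = c(1, 3)))
as_abundances <- function(x) {
  x <- as_tibble(x)
  if (!"p" %in% names(x) && "abundance" %in% names(x)) {
    x <- dplyr::rename(x, p = "abundance")
  }
  if (!all(c("species", "p") %in% names(x))) {
    abort("abundance table needs columns `species` and `p` (or `abundance`)")
  }
  x$species <- as.character(x$species)
  if (anyDuplicated(x$species)) {
    abort("duplicate species labels in abundance table")
  }
  if (!is.numeric(x$p) || anyNA(x$p)) abort("abundances must be numeric and non-missing")
  if (any(x$p < 0)) abort("negative abundances are not allowed")
  if (all(x$p == 0)) abort("all abundances are zero")
  if (any(x$p == 0)) {
    warn(sprintf("dropping %d species with zero abundance", sum(x$p == 0)))
    x <- x[x$p > 0, ]
  }
  x$p <- x$p / sum(x$p)
  x[, c("species", "p")]
}

#' Read a relative-abundance table from a delimited file
#'
#' Expects a header with a species-id column and an abundance column
#' (`species,abundance` or `species,p`); comma- and tab-delimited files are
#' both accepted. Raw counts or biomass are fine: the column is normalised to
#' relative abundances at load time, preserving row order.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `species` and `p` (summing to one).
#' @export
load_abundances <- function(path) {
  x <- readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE)
  as_abundances(x)
}

guess_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Tally species counts from a sampling sequence
#'
#' Counts how many individuals of each species appear in an ordered sampling
#' sequence. Every species of the universe is reported, including those with
#' zero observations, so counts align with abundance vectors and distance
#' matrices downstream.
#'
#' @param seq Character vector of species labels in sampling order.
#' @param universe Character vector of all species labels; defaults to the
#'   distinct labels present in `seq`.
#' @return A tibble with columns `species` and `n`; `sum(n)` equals
#'   `length(seq)`.
#' @export
#' @examples
#' counts_from_sequence(c("a", "a", "b"), universe = c("a", "b", "c"))
counts_from_sequence <- function(seq, universe = unique(seq)) {
  seq <- as.character(seq)
  universe <- as.character(universe)
  if (length(seq) < 1L) abort("sequence must contain at least one individual")
  if (anyDuplicated(universe)) abort("species universe contains duplicates")
  outside <- setdiff(seq, universe)
  if (length(outside) > 0L) {
    abort(sprintf("labels outside the species universe: %s",
                  paste(utils::head(outside, 5L), collapse = ", ")))
  }
  n <- tabulate(factor(seq, levels = universe), nbins = length(universe))
  tibble(species = universe, n = as.integer(n))
}

#' Generate a synthetic relative-abundance vector
#'
#' Three abundance models are available: `uniform` (all species equal),
#' `geometric` (rank-ordered geometric decay, `p_i` proportional to
#' `shape^i`, `0 < shape < 1`; smaller values give stronger dominance) and
#' `lognormal` (abundances drawn from a log-normal with log-sd `shape` and
#' sorted in decreasing order). Geometric and log-normal series are the two
#' classical skewed species-abundance distributions and bracket the degree of
#' heterogeneity seen in real community samples.
#'
#' @param s Number of species.
#' @param model One of `"uniform"`, `"geometric"`, `"lognormal"`.
#' @param shape Model parameter (ignored for `uniform`).
#' @param seed Optional integer seed (only the log-normal model is random).
#' @return An abundance tibble (columns `species`, `p`).
#' @export
#' @examples
#' make_abundances(4, "uniform")
#' make_abundances(34, "geometric", shape = 0.9)
make_abundances <- function(s, model = c("uniform", "geometric", "lognormal"),
                            shape = 0.9, seed = NULL) {
  model <- match.arg(model)
  if (s < 1L) abort("need at least one species")
  w <- switch(model,
    uniform = rep(1, s),
    geometric = {
      if (!is.numeric(shape) || shape <= 0 || shape >= 1) {
        abort("geometric model needs 0 < shape < 1")
      }
      shape^seq_len(s)
    },
    lognormal = {
      if (!is.numeric(shape) || shape <= 0) abort("lognormal model needs shape > 0")
      if (!is.null(seed)) set.seed(seed)
      sort(stats::rlnorm(s, meanlog = 0, sdlog = shape), decreasing = TRUE)
    }
  )
  as_abundances(tibble(species = sprintf("sp%02d", seq_len(s)), p = w))
}
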