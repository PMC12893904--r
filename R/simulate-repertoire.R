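#' Simulate a TCR clonotype table
#'
#' Generates synthetic CDR3 amino-acid junctions for a chosen clone-size
#' distribution and returns an AIRR-style long table (one row per chain per
#' cell). Pairing is decided at the clone level: a clone carries either a
#' TRB junction alone or a fixed TRA/TRB pair, so all cells of a clone
#' share the same chain configuration and clone key.
#'
#' @param n_cells Number of cells (> 0).
#' @param clone_distribution `"uniform"` (equal clone sizes, exact when
#'   `n_cells` is divisible by `n_clones`), `"geometric"` (clone
#'   probabilities proportional to `(1 - prob)^(i-1)`), or `"powerlaw"`
#'   (proportional to `i^-exponent`).
#' @param n_clones Number of distinct clones.
#' @param prob Geometric decay parameter in (0, 1).
#' @param exponent Power-law exponent (larger = more skewed).
#' @param pair_rate Fraction of clones carrying a paired TRA chain.
#' @param run_id,treatment Metadata attached to every row.
#' @param seed Integer seed.
#' @return A list with `table` (tibble: `cell_id`, `chain`, `junction_aa`,
#'   `run_id`, `treatment`) and `truth` (tibble: `cell_id`, `clone_id`).
#' @examples
#' rep <- simulate_repertoire(40, "uniform", n_clones = 8, seed = 1)
#' dplyr::n_distinct(rep$truth$clone_id)
#' @export
simulate_repertoire <- function(n_cells,
                                clone_distribution = c("uniform",
                                                       "geometric",
                                                       "powerlaw"),
                                n_clones = 20,
                                prob = 0.2,
                                exponent = 1.5,
                                pair_rate = 0.7,
                                run_id = "run1",
                                treatment = NA_character_,
                                seed = 1L) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(n_clones, "n_clones", lower = 1)
  clone_distribution <- rlang::arg_match(clone_distribution)
  with_seed_or_current(seed, {
    assign_clone <- switch(
      clone_distribution,
      uniform = rep(seq_len(n_clones), length.out = n_cells),
      geometric = {
        p <- (1 - prob)^(seq_len(n_clones) - 1)
        sample.int(n_clones, n_cells, replace = TRUE, prob = p / sum(p))
      },
      powerlaw = {
        p <- seq_len(n_clones)^(-exponent)
        sample.int(n_clones, n_cells, replace = TRUE, prob = p / sum(p))
      }
    )
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    rand_junction <- function(prefix) {
      len <- sample(6:10, 1)
      paste0(prefix, paste(sample(aa, len, replace = TRUE), collapse = ""),
             "F")
    }
    trb <- vapply(seq_len(n_clones), function(i) rand_junction("CASS"),
                  character(1))
    paired <- runif(n_clones) < pair_rate
    tra <- ifelse(paired,
                  vapply(seq_len(n_clones),
                         function(i) rand_junction("CAV"), character(1)),
                  NA_character_)
    ids <- sprintf("%s_cell%05d", run_id, seq_len(n_cells))
    rows <- tibble(
      cell_id = rep(ids, times = 1 + paired[assign_clone]),
      chain = unlist(lapply(assign_clone, function(cl)
        if (paired[cl]) c("TRA", "TRB") else "TRB")),
      junction_aa = unlist(lapply(assign_clone, function(cl)
        if (paired[cl]) c(tra[cl], trb[cl]) else trb[cl])),
      run_id = run_id,
      treatment = treatment
    )
    list(
      table = rows,
      truth = tibble(cell_id = ids,
                     clone_id = sprintf("clone%03d", assign_clone))
    )
  })
}

#' Simulate antibody-derived tag (ADT) counts with a bimodal tetramer signal
#'
#' Counts are a two-component log-normal mixture rounded to integers:
#' a negative (background) and a positive (antigen-specific) mode. Ground
#' truth positivity flags are returned separately from the counts.
#'
#' @param n_cells Number of cells.
#' @param pos_fraction Fraction of truly positive cells in \[0, 1\].
#' @param neg_logmean,pos_logmean Log-scale means of the two modes
#'   (`pos_logmean > neg_logmean`).
#' @param log_sd Common log-scale standard deviation.
#' @param tag Tag (column) name.
#' @param seed Integer seed.
#' @return A list with `counts` (cells x 1 integer matrix) and `truth`
#'   (tibble: `cell_id`, `positive`).
#' @examples
#' adt <- simulate_adt(100, pos_fraction = 0.1, seed = 1)
#' mean(adt$truth$positive)
#' @export
simulate_adt <- function(n_cells,
                         pos_fraction = 0.1,
                         neg_logmean = log(5),
                         pos_logmean = log(150),
                         log_sd = 0.5,
                         tag = "tetramer",
                         seed = 1L) {
  check_number(pos_fraction, "pos_fraction", lower = 0, upper = 1,
               class = "immunokit_bad_fraction")
  if (pos_logmean <= neg_logmean) {
    abort_bad_arg("`pos_logmean` must exceed `neg_logmean`.",
                  "immunokit_bad_config")
  }
  check_number(log_sd, "log_sd", lower = 0, strict_lower = TRUE)
  with_seed_or_current(seed, {
    positive <- runif(n_cells) < pos_fraction
    mu <- ifelse(positive, pos_logmean, neg_logmean)
    counts <- matrix(round(rlnorm(n_cells, meanlog = mu, sdlog = log_sd)),
                     ncol = 1)
    ids <- sprintf("cell%05d", seq_len(n_cells))
    dimnames(counts) <- list(ids, tag)
    list(counts = counts,
         truth = tibble(cell_id = ids, positive = positive))
  })
}
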