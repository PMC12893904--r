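# internal: expression values used for ligand-receptor scoring.
# Uses the normalised slot when present, otherwise log1p of raw counts
# (the usual log-normalised convention for communication scores).
lr_values <- function(expr) {
  if (!inherits(expr, "expr_set")) {
    abort_bad_arg("`expr` must be an expr_set.", "immunokit_bad_matrix")
  }
  if (!is.null(expr$norm)) expr$norm else log1p(expr$counts)
}

lr_check_pair <- function(expr, ligand, receptor, sender, receiver) {
  v <- lr_values(expr)
  for (g in c(ligand, receptor)) {
    if (!g %in% colnames(v)) {
      abort_bad_arg(sprintf("gene '%s' is absent from the matrix.", g),
                    "immunokit_gene_absent")
    }
  }
  if (!"cell_type" %in% names(expr$cells)) {
    abort_bad_arg("cell metadata needs a `cell_type` column.",
                  "immunokit_bad_matrix")
  }
  for (ty in c(sender, receiver)) {
    if (!ty %in% expr$cells$cell_type) {
      abort_bad_arg(sprintf("cell type '%s' is absent.", ty),
                    "immunokit_type_absent")
    }
  }
  v
}

#' Mean ligand-receptor communication score
#'
#' The arithmetic average of (i) the mean ligand expression over sender
#' cells and (ii) the mean receptor expression over receiver cells, on
#' log-normalised expression — the standard mean-expression convention of
#' cell-cell communication frameworks.
#'
#' @param expr An [expr_set]; the normalised slot is used when present,
#'   otherwise `log1p(counts)`.
#' @param ligand,receptor Gene names.
#' @param sender,receiver Cell-type labels (senders express the ligand,
#'   receivers the receptor).
#' @return A single numeric score.
#' @examples
#' m <- matrix(c(2, 2, 0, 0, 0, 0, 4, 4), 4, 2,
#'             dimnames = list(paste0("c", 1:4), c("Lig", "Rec")))
#' es <- expr_set(m, data.frame(cell_id = paste0("c", 1:4),
#'                              cell_type = c("S", "S", "R", "R")))
#' es$norm <- m # already-normalised toy values
#' lr_mean_score(es, "Lig", "Rec", "S", "R")
#' @export
lr_mean_score <- function(expr, ligand, receptor, sender, receiver) {
  v <- lr_check_pair(expr, ligand, receptor, sender, receiver)
  is_s <- expr$cells$cell_type == sender
  is_r <- expr$cells$cell_type == receiver
  (mean(v[is_s, ligand]) + mean(v[is_r, receptor])) / 2
}

#' Permutation test for a ligand-receptor score
#'
#' Permutes cell-type labels over cells (within each age group when the
#' metadata carries an `age` column, so the null preserves age composition)
#' and recomputes the mean communication score. The one-sided p-value uses
#' the add-one rule `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`,
#' so it is never zero and has resolution `1 / (n_perm + 1)`.
#'
#' @inheritParams lr_mean_score
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return One-row tibble: `ligand`, `receptor`, `sender`, `receiver`,
#'   `age`, `mean_value`, `p_perm`, `perm_mean` (the permutation null
#'   mean, a diagnostic), `n_perm`.
#' @export
lr_permutation_test <- function(expr, ligand, receptor, sender, receiver,
                                n_perm = 999, seed = 1L) {
  if (n_perm < 99) {
    abort_bad_arg("`n_perm` must be >= 99.", "immunokit_bad_config")
  }
  v <- lr_check_pair(expr, ligand, receptor, sender, receiver)
  labs <- expr$cells$cell_type
  if (sum(labs == sender) < 2 || sum(labs == receiver) < 2) {
    abort_bad_arg("need >= 2 cells of both sender and receiver types.",
                  "immunokit_too_few_cells")
  }
  lig <- v[, ligand]
  rec <- v[, receptor]
  obs <- (mean(lig[labs == sender]) + mean(rec[labs == receiver])) / 2
  strata <- if ("age" %in% names(expr$cells)) {
    split(seq_along(labs), expr$cells$age)
  } else {
    list(seq_along(labs))
  }
  perm <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(i) {
      pl <- labs
      for (idx in strata) pl[idx] <- labs[idx][sample.int(length(idx))]
      (mean(lig[pl == sender]) + mean(rec[pl == receiver])) / 2
    }, numeric(1))
  })
  ages <- if ("age" %in% names(expr$cells)) unique(expr$cells$age) else
    NA_real_
  tibble(
    ligand = ligand, receptor = receptor,
    sender = sender, receiver = receiver,
    age = if (length(ages) == 1) ages else NA_real_,
    mean_value = obs,
    p_perm = (1 + sum(perm >= obs)) / (n_perm + 1),
    perm_mean = mean(perm),
    n_perm = n_perm
  )
}

#' Spearman age trend of ligand-receptor scores with Bonferroni correction
#'
#' For each interaction, rank-correlates the mean communication score with
#' age (midranks for ties; exact p-value by enumeration for up to 9 ages,
#' t approximation beyond), Bonferroni-corrects over `m` tested
#' interactions, and categorises each interaction as `"increasing"`,
#' `"decreasing"` (sign of the correlation with corrected p below
#' `alpha`), or `"flat"`.
#'
#' @param scores Tibble with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `age`, `mean_value`; >= 3 ages per interaction.
#' @param m Number of tested interactions for the Bonferroni factor;
#'   defaults to the number of distinct interactions in `scores`.
#' @param alpha Significance threshold on the corrected p-value.
#' @return Tibble with one row per interaction: `spearman_r`, `p`,
#'   `p_bonferroni`, `category`, `n`.
#' @export
lr_age_trend <- function(scores, m = NULL, alpha = 0.05) {
  scores <- as_tibble(scores)
  need <- c("ligand", "receptor", "sender", "receiver", "age",
            "mean_value")
  if (!all(need %in% names(scores))) {
    abort_bad_arg(sprintf("`scores` needs columns: %s.",
                          paste(need, collapse = ", ")),
                  "immunokit_bad_config")
  }
  keys <- c("ligand", "receptor", "sender", "receiver")
  if (is.null(m)) m <- nrow(dplyr::distinct(scores[keys]))
  if (m < 1) abort_bad_arg("`m` must be >= 1.", "immunokit_bad_config")
  scores %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3) {
        abort_bad_arg("need >= 3 ages per interaction.",
                      "immunokit_bad_config")
      }
      if (sd(df$mean_value) == 0 || sd(df$age) == 0) {
        abort_bad_arg("constant score or age: correlation undefined.",
                      "immunokit_undefined_correlation")
      }
      ties <- anyDuplicated(df$mean_value) || anyDuplicated(df$age)
      ct <- suppressWarnings(
        cor.test(df$age, df$mean_value, method = "spearman",
                 exact = n <= 9 && !ties)
      )
      tibble(spearman_r = unname(ct$estimate), p = ct$p.value, n = n)
    }) %>%
    ungroup() %>%
    mutate(
      p_bonferroni = pmin(1, m * .data$p),
      category = dplyr::case_when(
        .data$p_bonferroni < alpha & .data$spearman_r > 0 ~ "increasing",
        .data$p_bonferroni < alpha & .data$spearman_r < 0 ~ "decreasing",
        TRUE ~ "flat"
      )
    )
}
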