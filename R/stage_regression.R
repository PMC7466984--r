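## Per-site multiple linear regression of binary mutation state on the 13
## stage methylation levels, with stepwise AIC model selection.
##
## This is a linear probability model (OLS on a 0/1 response): coefficients
## read directly as additive changes in mutation probability per unit
## methylation. A logistic fit is available as an option.

#' Build the regression design
#'
#' One row per common site; response `y` is 1 iff a CpG-context SNP lies at
#' the site, 0 otherwise; predictors are the raw stage methylation levels
#' in \[0, 1\].
#'
#' @param lmat level matrix from [level_matrix()] (or any `data.table` with
#'   `chrom`, `pos` and `m_<stage>` columns, e.g. latent ground-truth
#'   levels from the simulator).
#' @param mutated_sites `data.table` of (`chrom`, `pos`) positions carrying
#'   a qualifying SNP (e.g. CpG-type records of a classified catalog, or
#'   simulator ground truth).
#' @param stages stage order (default the canonical 13).
#' @return `data.table` with `chrom`, `pos`, `y` and the predictor columns.
#' @export
build_design <- function(lmat, mutated_sites, stages = germline_stages()) {
  cols <- paste0("m_", stages)
  missing <- setdiff(cols, names(lmat))
  if (length(missing))
    stop("level matrix missing stages: ", paste(missing, collapse = ", "))
  if (any(!stats::complete.cases(lmat[, cols, with = FALSE])))
    stop("missing predictor values")
  out <- data.table::copy(lmat[, c("chrom", "pos", cols), with = FALSE])
  mut <- unique(data.table::as.data.table(
    mutated_sites)[, c("chrom", "pos")])
  mut[, y := 1L]
  data.table::setkeyv(mut, c("chrom", "pos"))
  data.table::setkeyv(out, c("chrom", "pos"))
  out[, y := ifelse(is.na(mut[out, y]), 0L, 1L)]
  data.table::setcolorder(out, c("chrom", "pos", "y"))
  out[]
}

## formula over all m_<stage> predictors present in a design; env must hold
## the model data so stats::step can re-evaluate refits
.design_formula <- function(design, env = parent.frame()) {
  preds <- grep("^m_", names(design), value = TRUE)
  stats::as.formula(paste("y ~", paste(preds, collapse = " + ")), env = env)
}

.coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.table::data.table(
    term = sub("^m_", "", rownames(sm)),
    estimate = sm[, 1], se = sm[, 2], t = sm[, 3], p_value = sm[, 4]
  )
}

#' Ordinary least-squares fit of the mutation design
#'
#' OLS with intercept, classical standard errors, two-sided p-values from
#' the t distribution.
#'
#' @param design output of [build_design()].
#' @param logistic fit a logistic model instead (option; default `FALSE`).
#' @return object of class `stage_fit`: list with `coefficients`
#'   (`data.table`: term, estimate, se, t, p_value), `aic`, `n`, `terms`
#'   (selected predictor stages) and the underlying `fit`.
#' @export
fit_ols <- function(design, logistic = FALSE) {
  df <- as.data.frame(design[, -c("chrom", "pos")])
  fml <- .design_formula(design)
  fit <- if (logistic) {
    stats::glm(fml, data = df, family = stats::binomial())
  } else {
    stats::lm(fml, data = df)
  }
  if (!logistic && any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(sub("^m_", "", bad), collapse = ", "))
  }
  structure(list(coefficients = .coef_table(fit),
                 aic = stats::AIC(fit), n = nrow(df),
                 terms = sub("^m_", "",
                             grep("^m_", names(stats::coef(fit)), value = TRUE)),
                 fit = fit),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("stage_fit on", x$n, "sites; AIC =", format(x$aic), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Stepwise AIC model selection
#'
#' Greedy add/drop steps (direction both) minimising AIC, starting from
#' the full model, until no move improves AIC; deterministic given the
#' design. The selected model is refitted and reported like [fit_ols()].
#'
#' @param design output of [build_design()].
#' @param full optional `stage_fit` of the full model from [fit_ols()],
#'   reused as the starting point instead of refitting.
#' @param trace print the step trace (default `FALSE`).
#' @return a `stage_fit` for the selected model, with `terms` holding the
#'   retained stages.
#' @export
stepwise_select <- function(design, full = NULL, trace = FALSE) {
  df <- as.data.frame(design[, -c("chrom", "pos")])
  full <- if (is.null(full)) {
    stats::lm(.design_formula(design), data = df)
  } else {
    stopifnot(inherits(full, "stage_fit"))
    full$fit
  }
  environment(full$terms) <- environment()
  sel <- stats::step(full, scope = list(lower = ~1,
                                        upper = stats::formula(full)),
                     direction = "both", trace = as.integer(trace), k = 2)
  structure(list(coefficients = .coef_table(sel),
                 aic = stats::AIC(sel), n = nrow(df),
                 terms = sub("^m_", "",
                             grep("^m_", names(stats::coef(sel)), value = TRUE)),
                 fit = sel),
            class = "stage_fit")
}

#' Combined full / stepwise coefficient table
#'
#' One row per stage in canonical order: full-model estimate, SE and
#' p-value, plus the stepwise estimate (`NA` when the stage was dropped).
#'
#' @param full a `stage_fit` from [fit_ols()].
#' @param stepped a `stage_fit` from [stepwise_select()].
#' @param stages stage order (default the canonical 13).
#' @return `data.table` with `stage`, `estimate`, `se`, `p_value`,
#'   `stepwise_estimate`.
#' @export
regression_table <- function(full, stepped, stages = germline_stages()) {
  fc <- full$coefficients
  sc <- stepped$coefficients
  data.table::data.table(
    stage = stages,
    estimate = fc$estimate[match(stages, fc$term)],
    se = fc$se[match(stages, fc$term)],
    p_value = fc$p_value[match(stages, fc$term)],
    stepwise_estimate = sc$estimate[match(stages, sc$term)]
  )
}
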