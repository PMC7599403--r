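# Treatment-level statistics for the 2 x 2 x 3 factorial Rusitec design:
# least-squares means per factor, type-III F-tests for main effects and
# interactions, and Pearson correlation tables. The experimental run enters
# as an additive fixed block (equivalent point estimates to a run-random
# mixed model when the design is balanced).

.design_factors <- c("osmolality", "temperature", "betaine")

#' Balanced 2 x 2 x 3 factorial Rusitec design table
#'
#' One row per fermenter and run: each run carries all 12 treatment cells
#' (2 osmolalities x 2 temperatures x 3 betaine levels) once, so n = `n_runs`
#' per cell.
#'
#' @param n_runs number of experimental runs.
#' @return data frame with columns `run`, `fermenter`, `osmolality`
#'   (`normal`/`hyper`), `temperature` (`39.5`/`42`), `betaine`
#'   (`control`/`low`/`high`), all factors.
#' @export
rusitec_design <- function(n_runs = 6) {
  cells <- expand.grid(osmolality = c("normal", "hyper"),
                       temperature = c("39.5", "42"),
                       betaine = c("control", "low", "high"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_runs), function(r)
    cbind(run = r, fermenter = seq_len(nrow(cells)), cells)))
  out$run <- factor(out$run)
  out$fermenter <- factor(out$fermenter)
  out$osmolality <- factor(out$osmolality, levels = c("normal", "hyper"))
  out$temperature <- factor(out$temperature, levels = c("39.5", "42"))
  out$betaine <- factor(out$betaine, levels = c("control", "low", "high"))
  out
}

.check_design <- function(design) {
  needed <- c("run", "fermenter", .design_factors)
  if (!all(needed %in% names(design)))
    stop("design needs columns: ", paste(needed, collapse = ", "))
  for (v in needed) design[[v]] <- factor(design[[v]])
  cells <- table(design[.design_factors])
  if (any(cells == 0))
    stop("empty treatment cell(s) in the design; cannot estimate the ",
         "full factorial")
  if (length(unique(as.vector(table(design[c("run", .design_factors)])))) > 1)
    warning("design is unbalanced; LS means are model-based, not ",
            "arithmetic marginal means")
  design
}

#' Fit the factorial model and extract LS means and effect tests
#'
#' Fits an ordinary-least-squares linear model with the experimental run as
#' an additive block plus the full osmolality x temperature x betaine
#' factorial, then extracts least-squares (model-adjusted marginal) means
#' per factor level and type-III F-tests for the three main effects, the
#' three 2-way interactions and the 3-way interaction. Repeated records per
#' fermenter-run (e.g. daily measurements) are averaged before fitting.
#'
#' @param response numeric vector, one value per row of `design`.
#' @param design data frame with columns `run`, `fermenter`, `osmolality`,
#'   `temperature`, `betaine` (see [rusitec_design()]).
#' @return object of class `factorial_fit`: list with `model` (the `lm`
#'   fit), `lsmeans` (data frame: factor, level, lsmean, se), `anova`
#'   (data frame: effect, F, p_value, label with significance at P <= 0.05
#'   and tendency at 0.05 < P <= 0.10), and `data` (the averaged records).
#' @examples
#' d <- rusitec_design(3)
#' y <- rnorm(nrow(d)) + 2 * (d$osmolality == "hyper")
#' fit_factorial(y, d)
#' @export
fit_factorial <- function(response, design) {
  design <- .check_design(design)
  if (length(response) != nrow(design))
    stop("'response' must have one value per design row")
  dat <- design[c("run", "fermenter", .design_factors)]
  dat$y <- as.numeric(response)
  # average a fermenter's repeated daily records before fitting
  key <- interaction(dat$run, dat$fermenter, drop = TRUE)
  if (anyDuplicated(key)) {
    dat <- do.call(rbind, lapply(split(dat, key), function(g) {
      g$y[1] <- mean(g$y); g[1, ]
    }))
    rownames(dat) <- NULL
  }
  ctr <- lapply(dat[c("run", .design_factors)],
                function(f) stats::contr.sum(nlevels(f)))
  model <- stats::lm(y ~ run + osmolality * temperature * betaine,
                     data = dat, contrasts = ctr)
  lsm <- do.call(rbind, lapply(.design_factors, function(f) {
    em <- as.data.frame(suppressMessages(emmeans::emmeans(model, f)))
    data.frame(factor = f, level = as.character(em[[1]]),
               lsmean = em$emmean, se = em$SE)
  }))
  effects_order <- c("osmolality", "temperature", "betaine",
                     "osmolality:temperature", "osmolality:betaine",
                     "temperature:betaine",
                     "osmolality:temperature:betaine")
  if (stats::sigma(model) <=
        sqrt(.Machine$double.eps) * max(1, mean(abs(dat$y)))) {
    # (near-)constant response: no residual variation, no evidence of effects
    keep <- effects_order
    fval <- rep(NA_real_, length(keep))
    p <- rep(1, length(keep))
  } else {
    a3 <- car::Anova(model, type = 3)
    keep <- setdiff(rownames(a3), c("(Intercept)", "run", "Residuals"))
    p <- a3[keep, "Pr(>F)"]
    fval <- a3[keep, "F value"]
  }
  anova_tab <- data.frame(
    effect = keep, F = fval, p_value = p,
    label = ifelse(p <= 0.05, "significant",
                   ifelse(p <= 0.10, "tendency", "")))
  rownames(anova_tab) <- NULL
  structure(list(model = model, lsmeans = lsm, anova = anova_tab,
                 data = dat),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, digits = 3, ...) {
  cat("Factorial fit (run block + osmolality x temperature x betaine)\n")
  cat("LS means:\n")
  lsm <- x$lsmeans
  lsm$lsmean <- signif(lsm$lsmean, digits + 2)
  lsm$se <- signif(lsm$se, digits)
  print(lsm, row.names = FALSE)
  cat("Effects (type III):\n")
  a <- x$anova
  a$F <- signif(a$F, digits)
  a$p_value <- signif(a$p_value, digits)
  print(a, row.names = FALSE)
  invisible(x)
}

#' @export
summary.factorial_fit <- function(object, ...) {
  list(lsmeans = object$lsmeans, anova = object$anova,
       sigma = stats::sigma(object$model))
}

#' @export
coef.factorial_fit <- function(object, ...) stats::coef(object$model)

#' Estimated contrast between two levels of a design factor
#'
#' Difference of least-squares means (`level2` minus `level1`) with its
#' standard error and a t-based confidence interval.
#'
#' @param fit a [fit_factorial()] result.
#' @param factor one of `"osmolality"`, `"temperature"`, `"betaine"`.
#' @param levels character vector `c(level1, level2)`; the contrast is
#'   `level2 - level1`.
#' @param level confidence level.
#' @return one-row data frame with `estimate`, `se`, `df`, `lower`, `upper`.
#' @export
factor_contrast <- function(fit, factor = "osmolality",
                            levels = c("normal", "hyper"), level = 0.95) {
  stopifnot(inherits(fit, "factorial_fit"), factor %in% .design_factors,
            length(levels) == 2)
  em <- suppressMessages(emmeans::emmeans(fit$model, factor))
  lv <- as.character(as.data.frame(em)[[1]])
  w <- stats::setNames(rep(0, length(lv)), lv)
  if (!all(levels %in% lv)) stop("levels not found in factor '", factor, "'")
  w[levels[1]] <- -1; w[levels[2]] <- 1
  ct <- stats::confint(emmeans::contrast(em, list(contrast = w)),
                       level = level)
  data.frame(estimate = ct$estimate, se = ct$SE, df = ct$df,
             lower = ct$lower.CL, upper = ct$upper.CL)
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations between the columns of `x` (e.g. genus
#' relative abundances) and the columns of `y` (e.g. fermentation
#' parameters), with two-sided t-test P-values. Cells with P <= `alpha` are
#' flagged significant; `alpha` < P <= `tendency` as a tendency. Pairs with
#' zero variance yield `NA`.
#'
#' @param x,y numeric matrices or data frames with matching row order
#'   (paired samples).
#' @param alpha significance threshold.
#' @param tendency tendency threshold.
#' @return list with matrices `r`, `p` and character matrix `label`
#'   (rows = columns of `x`, columns = columns of `y`).
#' @export
pearson_matrix <- function(x, y, alpha = 0.05, tendency = 0.10) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("'x' and 'y' must have the same rows")
  if (nrow(x) < 3) stop("need at least 3 paired samples")
  r <- matrix(NA_real_, ncol(x), ncol(y),
              dimnames = list(colnames(x), colnames(y)))
  p <- r
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    ok <- stats::complete.cases(x[, i], y[, j])
    if (sum(ok) < 3) next
    if (stats::sd(x[ok, i]) == 0 || stats::sd(y[ok, j]) == 0) next
    ct <- stats::cor.test(x[ok, i], y[ok, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  label <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  label[!is.na(p) & p <= alpha] <- "significant"
  label[!is.na(p) & p > alpha & p <= tendency] <- "tendency"
  list(r = r, p = p, label = label)
}
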