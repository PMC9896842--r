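#' Linear mixed-effects model for amplitude summaries
#'
#' Relates a per-vessel amplitude summary (mean or maximum log amplitude, or
#' attenuation slope) to study group and covariates with random intercepts
#' absorbing the repeated structure: multiple measurements from the same eye
#' at various induced IOPs, and two eyes (laterality) within a participant.
#' Fixed effects are study group, age, sex, induced IOP and POAG status;
#' random intercepts are participant and eye-within-participant. Covariates
#' that are constant in the data (e.g. POAG in an all-normal cohort) are
#' dropped automatically. If the full random structure is singular or fails,
#' the model is refitted with an eye-level intercept only (warning logged);
#' distance from the disc centre is deliberately absent here because the
#' responses already integrate over distance (the slope response carries it).
#'
#' @param table cohort observation table (see [simulate_observations()] or
#'   [run_cohort()]): needs the response column plus `group_id`, `age`,
#'   `sex`, `induced_iop`, `poag`, `participant_id`, `eye_id`.
#' @param response one of `"mean_logamp"`, `"max_logamp"`, `"slope"`.
#' @param vessel_label `"vein"` or `"artery"`; rows are filtered to it.
#' @param reference reference study group (first factor level).
#' @return object of class `ppg_lmm`: the `lme4` fit, a Wald-z coefficient
#'   table, group marginal means (model predictions averaged over the
#'   observed covariate distribution) with descriptive per-eye SDs,
#'   residuals, and bookkeeping (`response`, `vessel_label`, `reference`,
#'   `singular_fallback`).
#' @export
fit_lmm <- function(table, response = c("mean_logamp", "max_logamp", "slope"),
                    vessel_label = "vein", reference = "N1_N1") {
  response <- match.arg(response)
  d <- table[table$vessel_label == vessel_label, , drop = FALSE]
  d <- d[is.finite(d[[response]]), , drop = FALSE]
  if (!nrow(d)) stop("no observations for vessel type ", vessel_label)
  if (length(unique(d$group_id)) < 2) {
    stop("at least two study groups are needed for a group comparison")
  }
  if (!reference %in% d$group_id) reference <- sort(unique(d$group_id))[1]
  d$group_id <- stats::relevel(factor(d$group_id), ref = reference)
  d$sex <- factor(d$sex)
  d$poag <- factor(as.logical(d$poag), levels = c(FALSE, TRUE))
  d$.y <- d[[response]]

  covars <- c("age", "sex", "induced_iop", "poag")
  keep <- vapply(covars, function(v) length(unique(d[[v]])) > 1, logical(1))
  fixed <- paste(c("group_id", covars[keep]), collapse = " + ")

  fit_with <- function(random) {
    f <- stats::as.formula(paste(".y ~", fixed, "+", random))
    lme4::lmer(f, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  singular_fallback <- FALSE
  model <- tryCatch(fit_with("(1 | participant_id) + (1 | eye_id)"),
                    error = function(e) NULL)
  if (is.null(model) || lme4::isSingular(model, tol = 1e-5)) {
    singular_fallback <- TRUE
    model <- fit_with("(1 | eye_id)")
    warning("full random structure singular; refitted with eye-level intercept only",
            call. = FALSE)
  }

  beta <- lme4::fixef(model)
  # degenerate fits (zero residual variance) can break vcov extraction;
  # report estimates with NA uncertainty rather than failing
  V <- tryCatch(as.matrix(stats::vcov(model)), error = function(e) {
    matrix(NA_real_, length(beta), length(beta),
           dimnames = list(names(beta), names(beta)))
  })
  se <- sqrt(diag(V))
  z <- beta / se
  coef_table <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )

  # marginal means: average model prediction with every row assigned to
  # group g (G-computation), expressed as a linear functional L_g' beta
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), data = d)
  X <- X[, names(beta), drop = FALSE]
  group_cols <- grep("^group_id", colnames(X), value = TRUE)
  groups <- levels(d$group_id)
  L <- matrix(0, length(groups), length(beta),
              dimnames = list(groups, names(beta)))
  base_row <- colMeans(X)
  for (g in groups) {
    row <- base_row
    row[group_cols] <- 0
    gc <- paste0("group_id", g)
    if (gc %in% group_cols) row[gc] <- 1
    L[g, ] <- row
  }
  mm <- as.vector(L %*% beta)
  mm_se <- sqrt(diag(L %*% V %*% t(L)))
  eye_means <- tapply(d$.y, list(d$group_id, d$eye_id), mean)
  sd_desc <- apply(eye_means, 1, stats::sd, na.rm = TRUE)
  marginal_means <- data.frame(
    group_id = groups, mean = mm, se = mm_se,
    sd_between_eyes = unname(sd_desc[groups]),
    stringsAsFactors = FALSE
  )

  structure(
    list(model = model, coefficients = coef_table,
         marginal_means = marginal_means, L = L, vcov = V, beta = beta,
         residuals = stats::residuals(model),
         response = response, vessel_label = vessel_label,
         reference = reference, singular_fallback = singular_fallback,
         data = d),
    class = "ppg_lmm"
  )
}

#' @export
print.ppg_lmm <- function(x, ...) {
  cat("ppg_lmm:", x$response, "~ group (+covariates),", x$vessel_label,
      "| reference", x$reference,
      if (x$singular_fallback) "[eye-only random intercept]" else "", "\n")
  print(x$marginal_means, digits = 4)
  invisible(x)
}

#' Pairwise group contrasts from a fitted mixed model
#'
#' Wald contrasts between group marginal means against a reference group,
#' flagged at the Bonferroni-corrected alpha for the family of comparisons
#' (five comparisons against each reference at a 0.05 family alpha gives the
#' 0.01 threshold).
#'
#' @param fit a `ppg_lmm`.
#' @param reference reference group (defaults to the fit's reference).
#' @param family_alpha family-wise alpha (default 0.05).
#' @param m number of comparisons in the family; defaults to the number of
#'   non-reference groups.
#' @return data.frame of `GroupComparison` rows: `response`, `vessel_label`,
#'   `group_a`, `group_b`, `estimate`, `se`, `p_value`, `significant`.
#' @export
pairwise_contrasts <- function(fit, reference = fit$reference,
                               family_alpha = 0.05, m = NULL) {
  groups <- fit$marginal_means$group_id
  if (!reference %in% groups) stop("group ", reference, " absent from fit")
  others <- setdiff(groups, reference)
  if (is.null(m)) m <- length(others)
  alpha <- bonferroni_alpha(family_alpha, m)
  out <- lapply(others, function(g) {
    l <- fit$L[g, ] - fit$L[reference, ]
    est <- sum(l * fit$beta)
    se <- sqrt(drop(t(l) %*% fit$vcov %*% l))
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(
      response = fit$response, vessel_label = fit$vessel_label,
      group_a = g, group_b = reference,
      estimate = est, se = se, p_value = p,
      significant = p < alpha, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  res
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha family-wise type-I error rate, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return `family_alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 5)  # 0.01
bonferroni_alpha <- function(family_alpha, m) {
  if (length(m) != 1 || m < 1) stop("m must be a single count >= 1")
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must lie in (0, 1)")
  }
  family_alpha / m
}

#' Normal quantile-quantile points for residual diagnostics
#'
#' Pairs the ordered residuals with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`, the standard normality check for the
#' log-amplitude models.
#'
#' @param residuals numeric vector, length >= 3.
#' @param plot logical; draw the q-q plot.
#' @return data.frame with `theoretical` and `sample` quantiles; attribute
#'   `degenerate` flags constant residuals.
#' @export
qq_points <- function(residuals, plot = FALSE) {
  n <- length(residuals)
  if (n < 3) stop("at least 3 residuals required")
  pts <- data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(residuals)
  )
  attr(pts, "degenerate") <- stats::sd(residuals) == 0
  if (attr(pts, "degenerate")) {
    warning("residuals are constant; q-q line is degenerate", call. = FALSE)
  }
  if (plot) {
    graphics::plot(pts$theoretical, pts$sample,
                   xlab = "Standard normal quantiles",
                   ylab = "Sample quantiles", main = "Residual q-q plot")
    graphics::abline(0, stats::sd(residuals), lty = 2)
  }
  pts
}
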