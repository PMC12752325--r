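#' Assemble the long analysis table for the group models
#'
#' Restricts block summaries to the analysis grid (default: first and last
#' block of the first and last session), joins each row with the
#' participant's FMA-UE score, and encodes Day and Block as treatment-coded
#' factors whose reference level is the first entry of `days` / `blocks`.
#' With the default 2x2 grid and a seven-participant cohort this yields the
#' 28-row design the group models are fitted on.
#'
#' @param summaries Tibble of block summaries ([summarize_block()] rows).
#' @param participants Participant metadata tibble with one `fma_ue` per
#'   participant.
#' @param days,blocks Integer vectors defining the analysis grid; the first
#'   element of each is the factor reference level.
#' @return Tibble with one row per (participant, day, block): `participant_id`,
#'   factors `day`, `block`, outcomes `bve_palm`, `mean_speed_palm`, and
#'   covariates `bve_trunk`, `bve_shoulder`, `fma_ue`.
#' @export
build_model_table <- function(summaries, participants,
                              days = c(1L, 5L), blocks = c(1L, 5L)) {
  sel <- summaries[summaries$day %in% days & summaries$block %in% blocks, ]
  missing_meta <- setdiff(unique(sel$participant_id),
                          participants$participant_id)
  if (length(missing_meta) > 0L) {
    stop("no metadata for participant(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(
    sel[c("participant_id", "day", "block", "bve_palm", "mean_speed_palm",
          "bve_trunk", "bve_shoulder")],
    participants[c("participant_id", "fma_ue")],
    by = "participant_id")
  out$day <- factor(paste("Day", out$day),
                    levels = paste("Day", days))
  out$block <- factor(paste("Block", out$block),
                      levels = paste("Block", blocks))
  out[order(out$participant_id, out$day, out$block), ]
}

lme_fixed_rhs <- "day * block + bve_trunk * bve_shoulder + fma_ue"

#' Fit a linear mixed-effects model for a hand outcome
#'
#' Fits, by restricted maximum likelihood, the group-level model
#' `outcome ~ Day * Block + trunk BVE * shoulder BVE + FMA-UE`
#' with random intercepts for participant and for day nested within
#' participant. The eight fixed-effect terms are reported with Wald 95%
#' confidence intervals and Wald-z p-values. Variance components give the
#' residual variance, the two random-intercept variances, their intraclass
#' correlation `ICC = sum(tau00) / (sum(tau00) + sigma2)`, and marginal /
#' conditional R-squared by the variance-decomposition definition (fixed
#' effects over total; fixed plus random over total).
#'
#' Incomplete rows are removed listwise (count reported). A singular or
#' non-converged fit is returned with `converged = FALSE` and a warning,
#' never as a silent success; a rank-deficient fixed-effects design is an
#' error naming the collinear columns.
#'
#' @param table Analysis table from [build_model_table()].
#' @param outcome `"bve_palm"` or `"mean_speed_palm"`.
#' @param center_covariates If `TRUE`, the continuous covariates (trunk BVE,
#'   shoulder BVE, FMA-UE) are mean-centered before fitting. Default `FALSE`
#'   (raw values, raw-product interaction).
#' @return An object of class `lme_fit`: a list with `outcome`,
#'   `coefficients` (tibble: `term`, `estimate`, `ci_low`, `ci_high`, `p`),
#'   `sigma2`, `tau00` (named vector), `icc`, `r2_marginal`,
#'   `r2_conditional`, `n_participants`, `n_days`, `n_observations`,
#'   `n_dropped_rows`, `converged`.
#' @export
fit_lme <- function(table, outcome = c("bve_palm", "mean_speed_palm"),
                    center_covariates = FALSE) {
  outcome <- match.arg(outcome)
  vars <- c(outcome, "participant_id", "day", "block",
            "bve_trunk", "bve_shoulder", "fma_ue")
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0L) {
    stop("analysis table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0L) {
    stop("analysis table is empty; nothing to fit", call. = FALSE)
  }
  complete <- stats::complete.cases(table[vars])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " incomplete row(s) removed before fitting")
  }
  dat <- table[complete, ]
  if (length(unique(dat$participant_id)) < 2L) {
    stop("at least 2 participants are required to fit the mixed model",
         call. = FALSE)
  }
  if (center_covariates) {
    for (v in c("bve_trunk", "bve_shoulder", "fma_ue")) {
      dat[[v]] <- dat[[v]] - mean(dat[[v]])
    }
  }

  fixed <- stats::as.formula(paste(outcome, "~", lme_fixed_rhs))
  X <- stats::model.matrix(fixed, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("fixed-effects design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  form <- stats::as.formula(paste(
    outcome, "~", lme_fixed_rhs,
    "+ (1 | participant_id) + (1 | participant_id:day)"))
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  converged <- length(msgs) == 0L && !singular
  if (!converged) {
    warning("mixed model for ", outcome,
            if (singular) " has a singular fit (a variance component is ~0)"
            else paste0(" did not converge cleanly: ",
                        paste(msgs, collapse = "; ")),
            call. = FALSE)
  }

  co <- as.data.frame(summary(fit)$coefficients)
  est <- co[["Estimate"]]
  se <- co[["Std. Error"]]
  z <- est / se
  zcrit <- stats::qnorm(0.975)
  coefficients <- tibble::tibble(
    term = rownames(co),
    estimate = est,
    ci_low = est - zcrit * se,
    ci_high = est + zcrit * se,
    p = 2 * stats::pnorm(-abs(z)))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  tau_rows <- vc[vc$grp != "Residual", ]
  tau00 <- stats::setNames(tau_rows$vcov, tau_rows$grp)
  # report day-within-participant first, participant second
  ord <- order(match(names(tau00), c("participant_id:day", "participant_id")))
  tau00 <- tau00[ord]
  names(tau00) <- sub("^participant_id:day$", "participant:day",
                      sub("^participant_id$", "participant", names(tau00)))
  icc <- sum(tau00) / (sum(tau00) + sigma2)

  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  total <- var_fixed + sum(tau00) + sigma2
  r2_marginal <- var_fixed / total
  r2_conditional <- (var_fixed + sum(tau00)) / total

  structure(
    list(outcome = outcome,
         coefficients = coefficients,
         sigma2 = sigma2,
         tau00 = tau00,
         icc = icc,
         r2_marginal = r2_marginal,
         r2_conditional = r2_conditional,
         n_participants = length(unique(dat$participant_id)),
         n_days = length(unique(dat$day)),
         n_observations = nrow(dat),
         n_dropped_rows = n_dropped,
         converged = converged),
    class = "lme_fit")
}

#' Render a fitted model report
#'
#' Produces either a plain-text grid (estimates, 95% CI, p per fixed effect,
#' then variance components, ICC, sample sizes and R-squared) or a
#' machine-readable JSON string carrying every field of the fit. Fixed
#' effects with p < 0.05 are starred in the text rendering; a
#' non-converged fit carries an explicit banner.
#'
#' @param fit An [fit_lme()] result.
#' @param format `"text"` or `"json"`.
#' @return A character scalar (text report or JSON).
#' @export
report <- function(fit, format = c("text", "json")) {
  stopifnot(inherits(fit, "lme_fit"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      c(unclass(fit)[setdiff(names(fit), c("coefficients", "tau00"))],
        list(coefficients = as.data.frame(fit$coefficients),
             tau00 = as.list(fit$tau00))),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)))
  }
  co <- fit$coefficients
  lines <- c(
    sprintf("Linear mixed-effects model: %s", fit$outcome),
    if (!fit$converged)
      "*** WARNING: fit did not converge cleanly (see `converged`) ***",
    sprintf("%-38s %10s  [%9s, %9s]  %8s", "Predictor", "Estimate",
            "CI low", "CI high", "p"),
    vapply(seq_len(nrow(co)), function(i) {
      sprintf("%-38s %10.3f  [%9.3f, %9.3f]  %8.4f%s",
              co$term[i], co$estimate[i], co$ci_low[i], co$ci_high[i],
              co$p[i], if (co$p[i] < 0.05) " *" else "")
    }, character(1)),
    "Random effects",
    sprintf("  sigma^2                 %10.3f", fit$sigma2),
    vapply(seq_along(fit$tau00), function(i) {
      sprintf("  tau00 %-18s %10.3f", names(fit$tau00)[i], fit$tau00[i])
    }, character(1)),
    sprintf("  ICC                     %10.3f", fit$icc),
    sprintf("N participants %d / days %d / observations %d",
            fit$n_participants, fit$n_days, fit$n_observations),
    sprintf("Marginal R2 / Conditional R2   %.3f / %.3f",
            fit$r2_marginal, fit$r2_conditional))
  paste(lines, collapse = "\n")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(report(x, "text"), "\n")
  invisible(x)
}

#' Reconstruct an `lme_fit` from its JSON report
#'
#' Inverse of `report(fit, "json")`: parses the JSON rendering back into an
#' `lme_fit` object with numerically identical fields.
#'
#' @param json JSON string (or path to a `.json` file).
#' @return An object of class `lme_fit`.
#' @export
as_lme_fit <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$coefficients <- tibble::as_tibble(x$coefficients)
  x$tau00 <- unlist(x$tau00)
  x$n_participants <- as.integer(x$n_participants)
  x$n_days <- as.integer(x$n_days)
  x$n_observations <- as.integer(x$n_observations)
  x$n_dropped_rows <- as.integer(x$n_dropped_rows)
  order_ref <- c("outcome", "coefficients", "sigma2", "tau00", "icc",
                 "r2_marginal", "r2_conditional", "n_participants", "n_days",
                 "n_observations", "n_dropped_rows", "converged")
  structure(x[order_ref], class = "lme_fit")
}
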