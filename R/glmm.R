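#' Build the long model frame for a guild occurrence model
#'
#' One response row per (survey, member species) with factors \code{bin}
#' (reference = PLEISTOCENE, or the earliest bin present), \code{species}
#' and \code{country}. The input must already be restricted to surveys
#' scoring the guild's full complement ([filterFullComplement()]), so every
#' retained survey contributes a 0/1 for every member and no bin x species
#' cell is partially empty. Bins without surveys are dropped with a
#' warning. With \code{level = "guild"} the response collapses to guild
#' presence (any member present) with one row per survey.
#'
#' @param x A \linkS4class{CoralOccurrence} after full-complement
#'   filtering.
#' @param level \code{"species"} (bin x species interaction) or
#'   \code{"guild"}.
#' @return A data.frame \code{y, bin, species, country, survey} with a
#'   \code{cells} attribute of per-cell counts.
#' @export
buildGuildDesign <- function(x, level = c("species", "guild")) {
  level <- match.arg(level)
  m <- occurrenceMatrix(x)
  if (anyNA(m)) stop("design requires a full-complement matrix (no NA cells)")
  cd <- surveyData(x)
  bins_present <- binLevels()[binLevels() %in% as.character(cd$bin)]
  empty <- setdiff(binLevels(), bins_present)
  if (length(empty) && length(empty) < length(binLevels())) {
    warning("bins with zero surveys dropped: ",
            paste(empty, collapse = ", "))
  }
  if (level == "guild") {
    y <- as.numeric(colSums(m) > 0)
    d <- data.frame(y = y,
                    bin = factor(as.character(cd$bin), levels = bins_present),
                    species = factor(rep("GUILD", ncol(m))),
                    country = factor(cd$country),
                    survey = cd$survey_id, stringsAsFactors = FALSE)
  } else {
    d <- data.frame(
      y = as.vector(m),
      bin = factor(rep(as.character(cd$bin), each = nrow(m)),
                   levels = bins_present),
      species = factor(rep(rownames(m), ncol(m)), levels = rownames(m)),
      country = factor(rep(cd$country, each = nrow(m))),
      survey = rep(cd$survey_id, each = nrow(m)),
      stringsAsFactors = FALSE)
  }
  attr(d, "cells") <- as.data.frame(table(bin = d$bin, species = d$species),
                                    stringsAsFactors = FALSE)
  d
}

#' Fit the binomial occurrence mixed model
#'
#' Fits presence ~ time bin x species group (dummy coding, earliest bin and
#' first species as reference) with a country random intercept on the
#' logit scale. The marginal likelihood integrates the country intercept
#' by adaptive Gauss-Hermite quadrature; \code{nAGQ = 1} is the Laplace
#' approximation (the default of the reference mixed-model software).
#' Engine \code{"glmer"} (lme4) supports any \code{nAGQ};
#' \code{"glmmTMB"} is an exact-Laplace engine via automatic
#' differentiation, considerably faster on large interaction models, and
#' agrees with glmer to numerical precision.
#'
#' @param design Model frame from [buildGuildDesign()].
#' @param engine \code{"glmer"} or \code{"glmmTMB"}.
#' @param nAGQ Integer >= 0 quadrature nodes (glmer only; 1 = Laplace).
#' @param guild Label recorded on the fit.
#' @return A \linkS4class{CoralGLMM}.
#' @export
fitOccurrenceModel <- function(design, engine = c("glmer", "glmmTMB"),
                               nAGQ = 1L, guild = "GUILD") {
  engine <- match.arg(engine)
  multi <- nlevels(design$species) > 1L
  fml <- if (multi) y ~ bin * species + (1 | country)
         else y ~ bin + (1 | country)
  if (engine == "glmer") {
    ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                               optCtrl = list(maxfun = 200000))
    fit <- lme4::glmer(fml, data = design, family = stats::binomial(),
                       nAGQ = nAGQ, control = ctrl)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma_u <- attr(lme4::VarCorr(fit)$country, "stddev")[[1]]
    conv <- fit@optinfo$conv$opt == 0 &&
      length(fit@optinfo$conv$lme4$messages) == 0
  } else {
    fit <- glmmTMB::glmmTMB(fml, data = design, family = stats::binomial())
    beta <- glmmTMB::fixef(fit)$cond
    V <- as.matrix(stats::vcov(fit)$cond)
    vc <- glmmTMB::VarCorr(fit)$cond$country
    sigma_u <- attr(vc, "stddev")[[1]]
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  }
  dimnames(V) <- list(names(beta), names(beta))
  methods::new("CoralGLMM", fit = fit, engine = engine, beta = beta,
               vcov = V, sigma_u = as.numeric(sigma_u),
               loglik = as.numeric(stats::logLik(fit)),
               converged = isTRUE(conv), nAGQ = as.integer(nAGQ),
               data = design, guild = guild,
               level = if (multi) "species" else "guild",
               cells = attr(design, "cells"))
}

#' @describeIn CoralGLMM-accessors fixed-effect coefficients (logit scale)
#' @export
fixedEffects <- function(fit) fit@beta

#' Accessors for CoralGLMM
#' @param fit A \linkS4class{CoralGLMM}.
#' @name CoralGLMM-accessors
NULL

#' @describeIn CoralGLMM-accessors country random-intercept SD
#' @export
countrySigma <- function(fit) fit@sigma_u

setMethod("show", "CoralGLMM", function(object) {
  cat("CoralGLMM [", object@engine, "] guild:", object@guild,
      " level:", object@level, "\n")
  cat("  rows:", nrow(object@data),
      " bins:", nlevels(object@data$bin),
      " species:", nlevels(object@data$species),
      " countries:", nlevels(object@data$country), "\n")
  cat(sprintf("  logLik: %.2f  sigma_u: %.3f  converged: %s\n",
              object@loglik, object@sigma_u, object@converged))
})

# fixed-effects design rows for every bin x species cell, at the
# random-effect mode (country intercept = 0)
.cellGrid <- function(fit) {
  d <- fit@data
  grid <- expand.grid(bin = levels(d$bin), species = levels(d$species),
                      stringsAsFactors = FALSE)
  grid$bin <- factor(grid$bin, levels = levels(d$bin))
  grid$species <- factor(grid$species, levels = levels(d$species))
  fml <- if (nlevels(d$species) > 1L) ~ bin * species else ~ bin
  L <- stats::model.matrix(fml, grid)
  list(grid = grid, L = L)
}

#' Estimated marginal occurrence by time bin
#'
#' For each bin x species cell the logit-scale linear predictor is
#' evaluated at the country random-effect mode (zero), with a Wald
#' standard error from the fixed-effect covariance; the fitted occurrence
#' proportion and confidence bounds are the inverse-logit images of the
#' symmetric link-scale interval. Guild-level curves average the member
#' species' link-scale predictions with equal weights before
#' back-transforming. Cells without data are omitted.
#'
#' @param fit A converged \linkS4class{CoralGLMM}.
#' @param level \code{"taxa"} (one curve per species), \code{"guild"}
#'   (equal-weight link-scale average over members), or \code{"both"}.
#' @param conf Confidence level (default 0.95).
#' @return data.frame: taxon, bin, link_estimate, link_se, proportion,
#'   ci_low, ci_high.
#' @export
marginalMeans <- function(fit, level = c("both", "taxa", "guild"),
                          conf = 0.95) {
  level <- match.arg(level)
  cg <- .cellGrid(fit)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- list()
  if (level %in% c("both", "taxa")) {
    for (sp in levels(cg$grid$species)) {
      sel <- cg$grid$species == sp
      rows[[sp]] <- data.frame(taxon = sp,
                               bin = as.character(cg$grid$bin[sel]),
                               L = I(cg$L[sel, , drop = FALSE]))
    }
  }
  if (level %in% c("both", "guild") && nlevels(fit@data$species) > 1L) {
    bins <- levels(cg$grid$bin)
    Lg <- t(vapply(bins, function(b) {
      colMeans(cg$L[cg$grid$bin == b, , drop = FALSE])
    }, numeric(ncol(cg$L))))
    rows[[fit@guild]] <- data.frame(taxon = fit@guild, bin = bins,
                                    L = I(Lg))
  }
  out <- do.call(rbind, rows)
  L <- unclass(as.matrix(out$L))
  est <- drop(L %*% fit@beta)
  se <- sqrt(rowSums((L %*% fit@vcov) * L))
  res <- data.frame(taxon = out$taxon, bin = out$bin,
                    link_estimate = est, link_se = se,
                    proportion = stats::plogis(est),
                    ci_low = stats::plogis(est - zq * se),
                    ci_high = stats::plogis(est + zq * se),
                    stringsAsFactors = FALSE, row.names = NULL)
  # omit cells with no observations (possible only in degenerate designs)
  cells <- fit@cells
  if (nrow(cells)) {
    empty <- cells[cells$Freq == 0, , drop = FALSE]
    if (nrow(empty)) {
      drop_key <- paste(empty$species, empty$bin)
      res <- res[!(paste(res$taxon, res$bin) %in% drop_key), , drop = FALSE]
    }
  }
  res
}

#' All pairwise time-bin contrasts with Tukey-style adjustment
#'
#' For each taxon (and the guild-average curve), every pair of time bins
#' is compared on the link scale: z = difference / SE(difference) using
#' the fixed-effect covariance. The familywise adjustment is the
#' single-step max-|z| method over the family's contrast correlation
#' matrix (the analogue of the Tukey test for correlated, possibly
#' unbalanced estimates): the adjusted p is the probability that the
#' maximum absolute contrast statistic under the multivariate-normal null
#' exceeds the observed |z|, evaluated by a seeded 40,000-draw Monte Carlo
#' integration (Monte-Carlo error below 0.002 near p = 0.05). The family
#' is all bin pairs within one taxon/curve; a one-contrast family reduces
#' exactly to the unadjusted two-sided z test.
#'
#' @param fit A converged \linkS4class{CoralGLMM}.
#' @param level Passed to [marginalMeans()].
#' @param adjust \code{"mvt"} (default) or \code{"none"}.
#' @param seed Integer seed for the (quasi-random) multivariate-normal
#'   integration.
#' @return data.frame: taxon, bin_a, bin_b, estimate (link-scale
#'   difference b - a), se, z, raw_p, adjusted_p.
#' @export
tukeyContrasts <- function(fit, level = "both", adjust = c("mvt", "none"),
                           seed = 1L) {
  adjust <- match.arg(adjust)
  cg <- .cellGrid(fit)
  mm <- marginalMeans(fit, level = level)
  set.seed(seed)
  out <- list()
  for (tx in unique(mm$taxon)) {
    sub <- mm[mm$taxon == tx, , drop = FALSE]
    bins <- sub$bin
    if (length(bins) < 2L) next
    if (tx %in% levels(cg$grid$species)) {
      Lt <- cg$L[cg$grid$species == tx, , drop = FALSE][
        match(bins, cg$grid$bin[cg$grid$species == tx]), , drop = FALSE]
    } else {
      Lt <- t(vapply(bins, function(b) {
        colMeans(cg$L[cg$grid$bin == b, , drop = FALSE])
      }, numeric(ncol(cg$L))))
    }
    pr <- utils::combn(length(bins), 2)
    D <- Lt[pr[2, ], , drop = FALSE] - Lt[pr[1, ], , drop = FALSE]
    Vc <- D %*% fit@vcov %*% t(D)
    se <- sqrt(diag(Vc))
    if (any(se < 1e-10)) {
      bad <- which(se < 1e-10)[1]
      stop("degenerate contrast between bins ", bins[pr[1, bad]], " and ",
           bins[pr[2, bad]])
    }
    est <- drop(D %*% fit@beta)
    z <- est / se
    raw <- 2 * stats::pnorm(-abs(z))
    adj <- raw
    if (adjust == "mvt" && length(z) > 1L) {
      R <- stats::cov2cor(Vc)
      # contrast families are rank-deficient (k cell means give C(k,2)
      # contrasts), so factor R by eigendecomposition rather than Cholesky
      ev <- eigen(R, symmetric = TRUE)
      Rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
      n_mc <- 40000L
      Zs <- abs(matrix(stats::rnorm(n_mc * nrow(R)), n_mc) %*% t(Rt))
      M <- Zs[cbind(seq_len(n_mc), max.col(Zs, ties.method = "first"))]
      adj <- vapply(abs(z), function(zz) mean(M >= zz), numeric(1))
      adj <- pmax(pmin(adj, 1), raw)  # adjusted never below raw
    }
    out[[tx]] <- data.frame(taxon = tx, bin_a = bins[pr[1, ]],
                            bin_b = bins[pr[2, ]], estimate = est, se = se,
                            z = z, raw_p = raw, adjusted_p = adj,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize occurrence trends per taxon and guild
#'
#' Condenses fitted curves and adjusted contrasts into the standard trend
#' table: fitted occurrence in the first and last bins, whether the
#' first-vs-last change is significant, the earliest bin differing
#' significantly from the Pleistocene baseline, the peak bin (maximum
#' fitted occurrence), and the earliest post-peak bin significantly below
#' the peak.
#'
#' @param mm Marginal means from [marginalMeans()].
#' @param contrasts Contrast table from [tukeyContrasts()].
#' @param alpha Significance level (default 0.05).
#' @return data.frame, one row per taxon/curve.
#' @export
trendSummary <- function(mm, contrasts, alpha = 0.05) {
  rows <- lapply(unique(mm$taxon), function(tx) {
    sub <- mm[mm$taxon == tx, , drop = FALSE]
    ord <- order(match(sub$bin, binLevels()))
    sub <- sub[ord, , drop = FALSE]
    ct <- contrasts[contrasts$taxon == tx, , drop = FALSE]
    first <- sub$bin[1]; last <- sub$bin[nrow(sub)]
    pair_p <- function(a, b) {
      hit <- (ct$bin_a == a & ct$bin_b == b) |
             (ct$bin_a == b & ct$bin_b == a)
      if (!any(hit)) NA_real_ else ct$adjusted_p[hit][1]
    }
    overall <- isTRUE(pair_p(first, last) < alpha)
    earliest_vs_base <- NA_character_
    if (first == "PLEISTOCENE") {
      for (b in sub$bin[-1]) {
        if (isTRUE(pair_p("PLEISTOCENE", b) < alpha)) {
          earliest_vs_base <- b; break
        }
      }
    }
    peak_i <- which.max(sub$proportion)
    peak <- sub$bin[peak_i]
    decline <- NA_character_
    if (peak_i < nrow(sub)) {
      for (j in seq(peak_i + 1L, nrow(sub))) {
        if (sub$proportion[j] < sub$proportion[peak_i] &&
            isTRUE(pair_p(peak, sub$bin[j]) < alpha)) {
          decline <- sub$bin[j]; break
        }
      }
    }
    data.frame(taxon = tx, start_proportion = sub$proportion[1],
               end_proportion = sub$proportion[nrow(sub)],
               overall_significant = overall,
               earliest_sig_change_vs_pleistocene = earliest_vs_base,
               peak_bin = peak, earliest_sig_decline_from_peak = decline,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
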