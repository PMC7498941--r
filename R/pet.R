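#' FLR composite region names
#'
#' The 16 Desikan–Killiany regions (8 bilateral pairs) entering the
#' frontal–lateral–retrosplenial (FLR) amyloid composite: precuneus, rostral
#' anterior cingulate, medial orbitofrontal, superior frontal, rostral middle
#' frontal, inferior parietal, inferior temporal and middle temporal, from
#' both hemispheres.
#'
#' @return Character vector of 16 `lh_`/`rh_`-prefixed region names.
#' @export
flr_regions <- function() {
  base <- c("precuneus", "rostralanteriorcingulate", "medialorbitofrontal",
            "superiorfrontal", "rostralmiddlefrontal", "inferiorparietal",
            "inferiortemporal", "middletemporal")
  c(paste0("lh_", base), paste0("rh_", base))
}

# Internal: per-subject named uptake vectors from a long ROI table.
split_uptake <- function(table) {
  fail_if(!all(c("subject", "region", "uptake") %in% names(table)),
          "ROI table needs columns subject, region, uptake")
  fail_if(any(table$uptake < 0), "ROI uptakes must be >= 0")
  split(setNames(table$uptake, table$region), table$subject)
}

# Internal: reference (cerebellar gray) uptake from one subject's vector.
reference_uptake <- function(u, reference) {
  fail_if(!reference %in% names(u), "missing reference region '%s'", reference)
  ref <- unname(u[[reference]])
  fail_if(ref <= 0, "reference uptake must be > 0")
  ref
}

#' Amyloid FLR DVR composite
#'
#' The continuous amyloid measure: the unweighted mean tracer uptake over the
#' 16 FLR regions, referenced to cerebellar gray.
#'
#' @param table data.frame with columns `subject`, `region`, `uptake`; must
#'   contain all 16 [flr_regions()] and the reference region per subject.
#' @param reference name of the reference region row (default
#'   `"cerebellum_cortex"`).
#' @return data.frame with columns `subject`, `dvr`.
#' @export
flr_dvr <- function(table, reference = "cerebellum_cortex") {
  per <- split_uptake(table)
  out <- lapply(names(per), function(s) {
    u <- per[[s]]
    miss <- setdiff(flr_regions(), names(u))
    fail_if(length(miss) > 0, "flr_dvr: subject %s missing ROI(s): %s",
            s, paste(miss, collapse = ", "))
    data.frame(subject = s,
               dvr = mean(u[flr_regions()]) / reference_uptake(u, reference))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Inferior-temporal tau SUVR
#'
#' Mean of the left/right inferior temporal uptakes divided by the cerebellar
#' gray reference.
#'
#' @inheritParams flr_dvr
#' @return data.frame with columns `subject`, `suvr`.
#' @export
it_suvr <- function(table, reference = "cerebellum_cortex") {
  per <- split_uptake(table)
  rois <- c("lh_inferiortemporal", "rh_inferiortemporal")
  out <- lapply(names(per), function(s) {
    u <- per[[s]]
    miss <- setdiff(rois, names(u))
    fail_if(length(miss) > 0, "it_suvr: subject %s missing hemisphere ROI(s): %s",
            s, paste(miss, collapse = ", "))
    data.frame(subject = s, suvr = mean(u[rois]) / reference_uptake(u, reference))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gaussian-mixture amyloid positivity cutoff
#'
#' Fits a two-component univariate Gaussian mixture by EM (k-means
#' initialization, multiple restarts, log-likelihood tolerance `tol`, at most
#' `max_iter` iterations) and returns the crossing point between the two
#' weighted component densities — the equal-posterior-probability point —
#' located between the two component means.
#'
#' @param x numeric vector of DVR values (>= 20 required).
#' @param n_components number of components; only 2 is supported.
#' @param n_restarts EM restarts from perturbed k-means initializations.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @param seed optional integer seed for the restart randomization (restored
#'   afterwards).
#' @return The cutoff (scalar), with attributes `means`, `sds`, `weights`,
#'   `loglik` (trace of the best restart), `iterations`.
#' @export
gmm_cutoff <- function(x, n_components = 2L, n_restarts = 10L, tol = 1e-8,
                       max_iter = 500L, seed = NULL) {
  fail_if(n_components != 2L, "gmm_cutoff: only 2 components supported")
  fail_if(length(x) < 20, "gmm_cutoff: need at least 20 values")
  fail_if(sd(x) == 0, "gmm_cutoff: degenerate input (all values identical)")
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- kmeans(x, centers = 2L, nstart = 1L)
      mu <- sort(km$centers[, 1]) * (1 + if (r == 1) 0 else rnorm(2, 0, 0.02))
      sg <- rep(max(sd(x) / 2, 1e-3), 2)
      w <- c(0.5, 0.5)
      ll_trace <- numeric(0)
      ll_old <- -Inf
      iter <- 0L
      repeat {
        iter <- iter + 1L
        dens <- cbind(w[1] * dnorm(x, mu[1], sg[1]), w[2] * dnorm(x, mu[2], sg[2]))
        tot <- rowSums(dens)
        ll <- sum(log(pmax(tot, .Machine$double.xmin)))
        ll_trace <- c(ll_trace, ll)
        g <- dens / pmax(tot, .Machine$double.xmin)
        nk <- colSums(g)
        fail_if(any(nk < 1e-8), "gmm_cutoff: degenerate component (vanishing weight)")
        mu <- colSums(g * x) / nk
        sg <- sqrt(colSums(g * (outer(x, mu, `-`))^2) / nk)
        fail_if(any(sg < 1e-8 * sd(x)),
                "gmm_cutoff: degenerate component (sigma -> 0)")
        w <- nk / length(x)
        if (abs(ll - ll_old) < tol) break
        fail_if(iter >= max_iter,
                "gmm_cutoff: EM did not converge after %d iterations", iter)
        ll_old <- ll
      }
      if (is.null(best) || ll > best$ll)
        best <- list(mu = mu, sg = sg, w = w, ll = ll, trace = ll_trace, iter = iter)
    }
    o <- order(best$mu)
    mu <- best$mu[o]; sg <- best$sg[o]; w <- best$w[o]
    f <- function(z) w[1] * dnorm(z, mu[1], sg[1]) - w[2] * dnorm(z, mu[2], sg[2])
    fail_if(f(mu[1]) <= 0 || f(mu[2]) >= 0,
            "gmm_cutoff: no density crossing between the component means")
    cut <- uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root
    structure(cut, means = mu, sds = sg, weights = w,
              loglik = best$trace, iterations = best$iter)
  })
}

#' Dichotomize amyloid burden
#'
#' `"high"` if DVR strictly exceeds the cutoff, `"low"` otherwise (boundary
#' values are low).
#'
#' @param dvr numeric vector of DVR values (> 0).
#' @param cutoff positivity threshold; the default 1.186 is the fixed
#'   published FLR threshold used for replication of the grouping.
#' @return factor with levels `low`, `high`.
#' @export
classify_amyloid <- function(dvr, cutoff = 1.186) {
  fail_if(any(dvr <= 0), "classify_amyloid: DVR must be > 0")
  factor(ifelse(dvr > cutoff, "high", "low"), levels = c("low", "high"))
}
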