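#' Configure a synthetic ICU site
#'
#' Defines the generative model for one synthetic site. Hourly dynamic values
#' for stay `s` and feature `f` follow
#' `x[s,f,t] = mu_f + u[s,f] + a[s,f,t]`, where `u[s,f] ~ N(0, sigma_f^2)` is
#' a stay-level random intercept (the between-stay component that carries
#' site shifts) and `a` is a stationary AR(1) fluctuation with autocorrelation
#' `rho_f` and standard deviation `within_ratio * sigma_f`. Sepsis onset is
#' assigned by a logistic hazard on the standardized stay-level latents of a
#' fixed subset of informative features, calibrated so the expected septic
#' fraction equals `prevalence`; because the hazard sees standardized latents
#' only, shifted sites differ in covariates but not in the label-generating
#' mechanism (covariate shift, not label shift). From six hours before onset
#' onward, septic stays receive an additional mean displacement of
#' `onset_effect` feature standard deviations on the informative features,
#' and their organ-dysfunction score steps up by at least 2 at onset.
#'
#' Defaults emulate a harmonized ICU cohort: 48 dynamic features (7 vitals,
#' fio2, urine output, 39 labs), autocorrelation 0.9 for the vitals-like block
#' and 0 for labs, hourly missingness 5% for vitals-like and 40% for labs,
#' sepsis prevalence 5.5% (the observed multi-site range is roughly 4.5–6.5%),
#' and stay lengths of 24–168 h with an exponentially decaying tail
#' (mean about 68 h).
#'
#' @param n_features Number of dynamic features (default 48).
#' @param features Feature names (default [default_features()], truncated or
#'   recycled-by-suffix to `n_features`).
#' @param mu,sigma Per-feature location and between-stay scale (scalars are
#'   recycled). `sigma > 0`.
#' @param rho Per-feature AR(1) autocorrelation in `[0, 1)`; default 0.9 for
#'   the first nine (vitals-like) features, 0 for the rest.
#' @param within_ratio Standard deviation of the hourly AR(1) fluctuation as a
#'   fraction of `sigma` (default 0.5).
#' @param missing_rate Per-feature probability that an hourly value is
#'   unobserved (MCAR); default 0.05 vitals-like, 0.40 labs.
#' @param prevalence Target fraction of stays developing sepsis, in (0, 0.5).
#' @param stay_min,stay_max,stay_mean_extra Stay-length distribution:
#'   `stay_min` plus a geometric-tailed draw truncated at `stay_max`, with the
#'   tail's mean set by `stay_mean_extra` (hours).
#' @param informative Names (or indices) of the features driving the onset
#'   hazard and receiving the onset displacement; default 8 clinically
#'   sepsis-relevant features.
#' @param onset_effect Mean displacement on informative features from
#'   (onset - 6 h) onward, in units of the feature's `sigma` (default 1.0).
#' @param hazard_beta Slope of the logistic onset hazard on the standardized
#'   latent summary (default 2).
#' @param seed Integer seed; every draw in [generate_site()] derives from it.
#'
#' @return An object of class `site_config`.
#' @export
site_config <- function(n_features = 48L,
                        features = NULL,
                        mu = 0, sigma = 1, rho = NULL,
                        within_ratio = 0.5,
                        missing_rate = NULL,
                        prevalence = 0.055,
                        stay_min = 24L, stay_max = 168L, stay_mean_extra = 44,
                        informative = NULL,
                        onset_effect = 1.0,
                        hazard_beta = 2,
                        seed = 1L) {
  n_features <- as.integer(n_features)
  if (n_features < 1) abort("n_features must be >= 1")
  if (is.null(features)) {
    base <- default_features()
    features <- if (n_features <= length(base)) base[seq_len(n_features)] else
      c(base, paste0("x", seq_len(n_features - length(base))))
  }
  stopifnot(length(features) == n_features)
  vitals_like <- seq_len(min(9L, n_features))
  if (is.null(rho)) {
    rho <- rep(0, n_features); rho[vitals_like] <- 0.9
  }
  if (is.null(missing_rate)) {
    missing_rate <- rep(0.40, n_features); missing_rate[vitals_like] <- 0.05
  }
  rec <- function(x) rep_len(x, n_features)
  mu <- rec(mu); sigma <- rec(sigma); rho <- rec(rho)
  missing_rate <- rec(missing_rate)
  if (any(sigma <= 0)) abort("sigma must be > 0")
  if (any(rho < 0 | rho >= 1)) abort("rho must be in [0, 1)")
  if (any(missing_rate < 0 | missing_rate >= 1)) abort("missing_rate must be in [0, 1)")
  if (prevalence <= 0 || prevalence >= 0.5) abort("prevalence must be in (0, 0.5)")
  if (is.null(informative)) {
    cand <- c("hr", "map", "resp", "temp", "lact", "crea", "wbc", "bili")
    informative <- intersect(cand, features)
    if (length(informative) == 0) informative <- features[seq_len(min(8L, n_features))]
  }
  if (is.numeric(informative)) informative <- features[informative]
  stopifnot(all(informative %in% features))
  onset_vec <- rep(0, n_features)
  onset_vec[match(informative, features)] <- rep_len(onset_effect, length(informative))

  structure(
    list(
      n_features = n_features,
      features = tibble(
        feature = features, mu = mu, sigma = sigma, rho = rho,
        missing_rate = missing_rate, onset_effect = onset_vec
      ),
      within_ratio = within_ratio,
      prevalence = prevalence,
      stay_min = as.integer(stay_min), stay_max = as.integer(stay_max),
      stay_mean_extra = stay_mean_extra,
      informative = informative,
      hazard_beta = hazard_beta,
      seed = as.integer(seed)
    ),
    class = "site_config"
  )
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config> ", x$n_features, " features, prevalence ",
      x$prevalence, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Shift a site configuration by a target effect size
#'
#' Returns a configuration whose per-feature population Cohen's d against the
#' reference equals `shift_d` on the scale the shift protocol measures:
#' per-stay feature means. The new scale is
#' `sigma'_f = sqrt(var_ratio_f) * sigma_f` and the new location is
#' `mu'_f = mu_f + shift_d_f * s_pooled_f`, where `s_pooled_f` is the pooled
#' standard deviation of per-stay means implied by the pair —
#' `sqrt((v_f + var_ratio_f * v_f) / 2)` with `v_f` the per-stay-mean
#' variance of the reference site (between-stay variance plus the exactly
#' computed contribution of the hourly AR(1) fluctuation; with
#' `within_ratio = 0` this reduces to the plain pooled `sigma`). All other
#' generator settings (including the label mechanism) are inherited
#' unchanged, so a reference/shifted pair differs only in covariate
#' distributions.
#'
#' @param reference A `site_config`.
#' @param shift_d Per-feature standardized mean shift (length `n_features`, or
#'   a scalar, or a named vector over a subset of features with 0 elsewhere).
#' @param var_ratio Per-feature variance multiplier (> 0), recycled likewise.
#' @param seed Seed for the shifted site (default `reference$seed + 1L`).
#' @return A new `site_config`.
#' @export
induce_shift <- function(reference, shift_d = 0, var_ratio = 1,
                         seed = reference$seed + 1L) {
  stopifnot(inherits(reference, "site_config"))
  nf <- reference$n_features
  expand <- function(x, what) {
    if (!is.null(names(x))) {
      out <- rep(if (what == "var_ratio") 1 else 0, nf)
      idx <- match(names(x), reference$features$feature)
      if (anyNA(idx)) abort(paste("unknown feature in", what))
      out[idx] <- unname(x)
      return(out)
    }
    if (length(x) == 1) return(rep(x, nf))
    if (length(x) != nf) abort(paste(what, "must have length n_features"))
    x
  }
  shift_d <- expand(shift_d, "shift_d")
  var_ratio <- expand(var_ratio, "var_ratio")
  if (any(var_ratio <= 0)) abort("var_ratio must be > 0")

  cfg <- reference
  sigma <- reference$features$sigma
  sigma2 <- sqrt(var_ratio) * sigma
  v_ref <- stay_mean_variance(reference)
  pooled <- sqrt((v_ref + var_ratio * v_ref) / 2)
  cfg$features$mu <- reference$features$mu + shift_d * pooled
  cfg$features$sigma <- sigma2
  cfg$seed <- as.integer(seed)
  cfg
}

# Sample stay lengths: stay_min + geometric-tailed extra hours truncated at
# stay_max, giving the short-stay-heavy length profile of ICU cohorts.
sample_stay_lengths <- function(n, config) {
  extra <- rgeom(n, prob = 1 / (config$stay_mean_extra + 1))
  pmin(config$stay_min + extra, config$stay_max)
}

# Exact pmf of the stay-length distribution above.
stay_length_pmf <- function(config) {
  p <- 1 / (config$stay_mean_extra + 1)
  L <- config$stay_min:config$stay_max
  k <- L - config$stay_min
  pmf <- p * (1 - p)^k
  pmf[length(pmf)] <- (1 - p)^k[length(k)]   # truncation mass at stay_max
  tibble(L = L, p = pmf)
}

# Variance of the mean of L consecutive AR(1) values with unit stationary
# variance: (L + 2 rho (L - 1 - L rho + rho^L) / (1 - rho)^2) / L^2.
ar1_mean_var_factor <- function(L, rho) {
  if (rho == 0) return(1 / L)
  (L + 2 * rho * (L - 1 - L * rho + rho^L) / (1 - rho)^2) / L^2
}

# Per-feature variance of the per-stay mean implied by a site config:
# between-stay sigma^2 plus the expected contribution of the hourly AR(1)
# fluctuation averaged over the stay-length distribution (missingness, which
# changes this only marginally, is ignored).
stay_mean_variance <- function(config) {
  pmf <- stay_length_pmf(config)
  map_dbl(seq_len(config$n_features), function(f) {
    rho <- config$features$rho[f]
    sigma <- config$features$sigma[f]
    cbar <- sum(pmf$p * map_dbl(pmf$L, ar1_mean_var_factor, rho = rho))
    sigma^2 * (1 + config$within_ratio^2 * cbar)
  })
}

#' Generate one synthetic site
#'
#' Draws a full cohort (static, dynamic, events, organ scores) from a
#' [site_config()], together with the generating truth. Every septic stay has
#' a culture draw and an antibiotic course of at least 72 h paired near the
#' onset (so strict Sepsis-3 labeling can recover it), and an organ-score
#' step of +2 or more at onset. Controls may carry short (< 72 h) antibiotic
#' courses, cultures without organ-score rise, or long courses without a
#' culture — none of which qualify as suspicion of infection. Fully
#' reproducible from `config$seed`.
#'
#' @param config A `site_config`.
#' @param n_stays Number of stays (> 0).
#' @return An object of class `generated_site`: a list with `cohort`
#'   (a [cohort_table()]), `truth` (tibble: `stay_id`, `septic`,
#'   `onset_hour`), `moments` (realized per-feature moments), and `config`.
#' @export
generate_site <- function(config, n_stays) {
  stopifnot(inherits(config, "site_config"))
  if (!is.numeric(n_stays) || n_stays <= 0) abort("n_stays must be > 0")
  n_stays <- as.integer(n_stays)
  set.seed(config$seed)

  ft <- config$features
  nf <- config$n_features
  stay_id <- seq_len(n_stays)
  span <- sample_stay_lengths(n_stays, config)

  static <- tibble(
    stay_id = stay_id,
    admission_time = round(runif(n_stays, 0, 8760), 3),
    age = round(pmin(pmax(rnorm(n_stays, 65, 15), 18), 100), 1),
    sex = rbinom(n_stays, 1, 0.5),
    height = round(rnorm(n_stays, 170, 10), 1),
    weight = round(rnorm(n_stays, 80, 15), 1)
  )

  # stay-level latent intercepts; standardized latents drive the onset hazard
  u <- matrix(rnorm(n_stays * nf), n_stays, nf) %*% diag(ft$sigma, nf)
  k <- length(config$informative)
  inf_idx <- match(config$informative, ft$feature)
  z <- rowSums(scale(u[, inf_idx, drop = FALSE],
                     center = FALSE, scale = ft$sigma[inf_idx])) / sqrt(k)

  # calibrate the hazard intercept so that mean septic probability hits the
  # configured prevalence on this cohort's latents
  beta <- config$hazard_beta
  a <- uniroot(function(a) mean(plogis(a + beta * z)) - config$prevalence,
               interval = c(-40, 10), tol = 1e-9)$root
  septic <- rbinom(n_stays, 1, plogis(a + beta * z)) == 1

  # onset placed at >= 8 h (survives the 6 h admission exclusion) and before
  # the final stay hour
  onset_hour <- rep(NA_integer_, n_stays)
  if (any(septic)) {
    lo <- 8L
    hi <- span - 2L
    onset_hour[septic] <- as.integer(lo + floor(runif(sum(septic)) * (hi[septic] - lo + 1L)))
  }

  # hourly AR(1) fluctuations, vectorized over stays x features per hour
  max_span <- max(span)
  sw <- config$within_ratio * ft$sigma
  innov_sd <- sw * sqrt(1 - ft$rho^2)
  X <- matrix(rnorm(n_stays * nf), n_stays, nf) %*% diag(sw, nf)  # stationary start
  onset_mat_base <- outer(rep(1, n_stays), ft$onset_effect * ft$sigma)
  dyn_chunks <- vector("list", max_span)
  for (t in seq_len(max_span)) {
    if (t > 1) {
      e <- matrix(rnorm(n_stays * nf), n_stays, nf) %*% diag(innov_sd, nf)
      X <- sweep(X, 2, ft$rho, `*`) + e
    }
    hour <- t - 1L
    idx <- which(span > hour)
    vals <- sweep(X[idx, , drop = FALSE] + u[idx, , drop = FALSE], 2, ft$mu, `+`)
    post <- septic[idx] & !is.na(onset_hour[idx]) & hour >= (onset_hour[idx] - 6L)
    if (any(post)) {
      vals[post, ] <- vals[post, ] + onset_mat_base[idx[post], , drop = FALSE]
    }
    dyn_chunks[[t]] <- cbind(stay_id = idx, hour = hour, vals)
  }
  dyn_mat <- do.call(rbind, dyn_chunks)
  ord <- order(dyn_mat[, "stay_id"], dyn_mat[, "hour"])
  dyn_mat <- dyn_mat[ord, , drop = FALSE]
  colnames(dyn_mat) <- c("stay_id", "hour", ft$feature)

  # realized moments before masking (truth for convergence checks)
  stay_means <- rowsum(dyn_mat[, ft$feature, drop = FALSE], dyn_mat[, "stay_id"]) / span
  moments <- tibble(
    feature = ft$feature,
    mean_hourly = colMeans(dyn_mat[, ft$feature, drop = FALSE]),
    mean_stay = colMeans(stay_means),
    sd_stay = apply(stay_means, 2, sd)
  )

  # MCAR missingness, feature-wise independent Bernoulli per hour
  vals <- dyn_mat[, ft$feature, drop = FALSE]
  if (any(ft$missing_rate > 0)) {
    m <- nrow(vals)
    miss <- matrix(runif(m * nf), m, nf) < rep(ft$missing_rate, each = m)
    vals[miss] <- NA_real_
  }
  dynamic <- as_tibble(cbind(as.data.frame(dyn_mat[, c("stay_id", "hour")]),
                             as.data.frame(vals)))
  dynamic$stay_id <- as.integer(dynamic$stay_id)
  dynamic$hour <- as.integer(dynamic$hour)

  # organ-dysfunction score: integer baseline, occasional downward dips for
  # controls, a sustained step of +2..+3 at onset for septic stays
  base_score <- sample(0:3, n_stays, replace = TRUE)
  os_rows <- map(stay_id, function(s) {
    L <- span[s]
    sc <- rep(base_score[s], L)
    dip <- runif(L) < 0.04
    sc[dip] <- pmax(sc[dip] - 1L, 0L)
    if (septic[s] && !is.na(onset_hour[s])) {
      rise <- sample(2:3, 1)
      from <- onset_hour[s] + 1L            # hours are 0-based; index = hour + 1
      sc[from:L] <- base_score[s] + rise
    }
    tibble(stay_id = s, hour = 0:(L - 1L), score = as.integer(sc))
  })
  organ_score <- list_rbind(os_rows)

  # events
  abx_list <- list(); cult_list <- list()
  for (s in stay_id) {
    if (septic[s] && !is.na(onset_hour[s])) {
      c_off <- sample(0:12, 1)
      culture_hour <- max(0L, onset_hour[s] - c_off)
      abx_start <- culture_hour + sample(0:24, 1)
      abx_end <- abx_start + 72L + sample(0:48, 1)
      cult_list[[length(cult_list) + 1]] <- tibble(stay_id = s, hour = culture_hour)
      abx_list[[length(abx_list) + 1]] <-
        tibble(stay_id = s, start_hour = abx_start, end_hour = abx_end)
    } else {
      r <- runif(3)
      if (r[1] < 0.15) {                     # short, non-qualifying course
        st <- sample(0:max(0L, span[s] - 5L), 1)
        abx_list[[length(abx_list) + 1]] <-
          tibble(stay_id = s, start_hour = st, end_hour = st + sample(12:48, 1))
      }
      if (r[2] < 0.15) {                     # culture without organ-score rise
        cult_list[[length(cult_list) + 1]] <-
          tibble(stay_id = s, hour = sample(0:(span[s] - 1L), 1))
      }
      if (r[3] < 0.05 && r[2] >= 0.15) {     # long course but no culture
        st <- sample(0:10, 1)
        abx_list[[length(abx_list) + 1]] <-
          tibble(stay_id = s, start_hour = st, end_hour = st + 72L + sample(0:24, 1))
      }
    }
  }
  bind_or_empty <- function(lst, cols) {
    if (length(lst) == 0) as_tibble(setNames(rep(list(integer()), length(cols)), cols))
    else list_rbind(lst)
  }
  abx <- bind_or_empty(abx_list, c("stay_id", "start_hour", "end_hour"))
  cultures <- bind_or_empty(cult_list, c("stay_id", "hour"))

  cohort <- cohort_table(
    static, dynamic, abx, cultures, organ_score,
    features = ft$feature,
    meta = list(seed = config$seed, generator = "sepshift-synth-v1",
                prevalence_target = config$prevalence),
    validate = FALSE
  )
  truth <- tibble(stay_id = stay_id, septic = septic, onset_hour = onset_hour)
  structure(list(cohort = cohort, truth = truth, moments = moments,
                 config = config),
            class = "generated_site")
}

#' @export
print.generated_site <- function(x, ...) {
  cat("<generated_site> ", n_stays(x$cohort), " stays, ",
      sum(x$truth$septic), " septic (",
      round(100 * mean(x$truth$septic), 2), "%)\n", sep = "")
  invisible(x)
}

#' Generate a source/target site pair under covariate shift
#'
#' Generates a reference ("source") site and a shifted ("target") site that
#' share the label-generating mechanism exactly — only covariate
#' distributions differ (see [induce_shift()]).
#'
#' @param reference A `site_config` for the source site.
#' @inheritParams induce_shift
#' @param n_source,n_target Stay counts (> 0).
#' @return Named list with `source` and `target`, each a `generated_site`.
#' @export
generate_pair <- function(reference, shift_d = 0, var_ratio = 1,
                          n_source, n_target) {
  if (missing(n_source) || n_source <= 0) abort("n_source must be > 0")
  if (missing(n_target) || n_target <= 0) abort("n_target must be > 0")
  target_cfg <- induce_shift(reference, shift_d, var_ratio,
                             seed = reference$seed + 1000L)
  list(source = generate_site(reference, n_source),
       target = generate_site(target_cfg, n_target))
}
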