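#' Configuration for a synthetic phantom cohort
#'
#' Defines the study conditions under which phantom cohorts are generated:
#' grid geometry, tumor size range, the latent risk model, exponential
#' event/censoring rates, and clinical missingness. The latent risk model is
#' a proportional-hazards construction: tumor volume and intra-tumor texture
#' heterogeneity (the standard deviation of Gaussian HU noise inside the
#' GTVp) contribute to a latent log-hazard via `risk_coefficients`; nodal
#' stage is drawn with probability increasing in that latent risk and adds
#' its own log-hazard term. Event times per endpoint are exponential with
#' rate `baseline_hazard_per_month * exp(risk)`, censored by an independent
#' exponential clock.
#'
#' @param n_patients Number of patients (positive integer).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param grid_shape Integer triple, voxel grid dimensions (x, y, z); the
#'   axial plane is (x, y) and z is the slice axis.
#' @param spacing_mm Positive real triple, voxel spacing in mm.
#' @param tumor_radius_range_mm Interval from which each ellipsoid semi-axis
#'   of the GTVp is drawn uniformly, in mm.
#' @param risk_coefficients Named vector with elements `volume`, `texture`,
#'   `n_stage`: log-hazard effects of standardized log tumor volume,
#'   standardized texture heterogeneity, and nodal stage.
#' @param baseline_hazard_per_month Exponential baseline event rate.
#' @param censoring_rate_per_month Exponential censoring rate.
#' @param horizon_months Dichotomization horizon (months), default 24.
#' @param persistence_prob Probability of the persistent-disease flag.
#' @param missing_clinical_prob Per-field probability that a clinical
#'   covariate is missing (missing completely at random).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          seed = 1337L,
                          grid_shape = c(64L, 64L, 48L),
                          spacing_mm = c(1, 1, 2),
                          tumor_radius_range_mm = c(8, 15),
                          risk_coefficients = c(volume = 1.0, texture = 0.8, n_stage = 0.3),
                          baseline_hazard_per_month = 0.02,
                          censoring_rate_per_month = 0.01,
                          horizon_months = 24,
                          persistence_prob = 0.05,
                          missing_clinical_prob = 0.05) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1,
            length(grid_shape) == 3L, length(spacing_mm) == 3L,
            length(tumor_radius_range_mm) == 2L,
            tumor_radius_range_mm[1] <= tumor_radius_range_mm[2])
  assert_pos(spacing_mm, "spacing_mm")
  assert_pos(baseline_hazard_per_month, "baseline_hazard_per_month")
  assert_pos(censoring_rate_per_month, "censoring_rate_per_month")
  assert_pos(horizon_months, "horizon_months")
  assert_prob(persistence_prob, "persistence_prob")
  assert_prob(missing_clinical_prob, "missing_clinical_prob")
  if (!all(c("volume", "texture", "n_stage") %in% names(risk_coefficients)))
    stop("risk_coefficients must name 'volume', 'texture' and 'n_stage'", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
    risk_coefficients = risk_coefficients,
    baseline_hazard_per_month = baseline_hazard_per_month,
    censoring_rate_per_month = censoring_rate_per_month,
    horizon_months = horizon_months,
    persistence_prob = persistence_prob,
    missing_clinical_prob = missing_clinical_prob
  ), class = "cohort_config")
}

#' Generate a synthetic phantom cohort
#'
#' Each patient is a body phantom (soft-tissue ellipsoid in air) with a
#' disconnected high-HU bed slab, an ellipsoidal GTVp whose size and texture
#' heterogeneity carry the latent risk signal, clinical covariates correlated
#' with risk, and per-endpoint (OS/LRC/FFDM) exponential event times with
#' independent exponential censoring.
#'
#' @param config A [cohort_config()].
#' @return A list of patient records (class `hn_cohort`). Each record holds
#'   `ct` (HU array), `gtvp_mask` ({0,1} integer array), `spacing`,
#'   `clinical` (list, possibly with `NA`s), `endpoints` (per endpoint a
#'   `time_months`/`event` pair), `persistent_disease` and `latent_risk`
#'   (the simulation-truth log-hazard, hidden from models).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$grid_shape; sp <- config$spacing_mm
  extent <- gs * sp
  r_max <- config$tumor_radius_range_mm[2]
  # the tumor (max diameter) plus a 4 mm margin must fit inside the grid
  if (any(2 * r_max + 4 > extent))
    stop("grid too small to contain the tumor plus margin; enlarge grid_shape",
         call. = FALSE)

  set.seed(config$seed)
  n <- config$n_patients
  rc <- config$risk_coefficients

  # -- scalar draws first (fixed RNG layout), images second --------------
  radii <- matrix(stats::runif(3 * n, config$tumor_radius_range_mm[1],
                               config$tumor_radius_range_mm[2]), ncol = 3)
  texture_sd <- stats::runif(n, 10, 60)          # HU noise sd inside GTVp
  vol <- 4 / 3 * pi * radii[, 1] * radii[, 2] * radii[, 3]
  safe_z <- function(x) {
    s <- stats::sd(x)
    if (length(x) < 2L || !is.finite(s) || s == 0) rep(0, length(x))
    else (x - mean(x)) / s
  }
  z_vol <- safe_z(log(vol))
  z_tex <- safe_z(texture_sd)
  latent <- rc[["volume"]] * z_vol + rc[["texture"]] * z_tex

  # nodal stage: ordered-logit draw with location = latent risk
  u <- latent + stats::rlogis(n)
  n_stage <- as.integer(cut(u, c(-Inf, -0.5, 1.0, 2.0, Inf))) - 1L   # 0..3
  risk <- latent + rc[["n_stage"]] * (n_stage - mean(n_stage))

  age <- pmin(90, pmax(30, round(stats::rnorm(n, 63, 9), 1)))
  sex <- stats::rbinom(n, 1, 0.82)               # 1 = male
  t_stage <- as.integer(cut(z_vol + stats::rlogis(n, scale = 0.8),
                            c(-Inf, -1, 0, 1, Inf)))
  hpv <- sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                prob = c(0.3, 0.2, 0.5))
  chemo <- stats::rbinom(n, 1, 0.6)
  persistent <- stats::rbinom(n, 1, config$persistence_prob)

  rate <- config$baseline_hazard_per_month * exp(risk)
  eps <- c("OS", "LRC", "FFDM")
  ev_time <- matrix(stats::rexp(3 * n, rate = rep(rate, each = 3)), nrow = 3,
                    dimnames = list(eps, NULL))
  cens <- matrix(stats::rexp(3 * n, rate = config$censoring_rate_per_month),
                 nrow = 3, dimnames = list(eps, NULL))

  miss <- matrix(stats::runif(6 * n) < config$missing_clinical_prob, nrow = 6)

  # offsets of the tumor center from the body center, in mm
  off <- cbind(stats::runif(n, -6, 6), stats::runif(n, -6, 6),
               stats::runif(n, -8, 8))

  xs <- (seq_len(gs[1]) - 0.5) * sp[1]
  ys <- (seq_len(gs[2]) - 0.5) * sp[2]
  zs <- (seq_len(gs[3]) - 0.5) * sp[3]
  body_c <- c(extent[1] / 2, 0.45 * extent[2], extent[3] / 2)
  body_ax <- c(0.42 * extent[1], 0.38 * extent[2], 0.48 * extent[3])
  ellipsoid <- function(center, semi) {
    ex <- ((xs - center[1]) / semi[1])^2
    ey <- ((ys - center[2]) / semi[2])^2
    ez <- ((zs - center[3]) / semi[3])^2
    outer(outer(ex, ey, "+"), ez, "+") <= 1
  }
  body <- ellipsoid(body_c, body_ax)
  bed <- ys > 0.92 * extent[2]                   # slab disconnected from body
  bed_arr <- array(rep(rep(bed, each = gs[1]), gs[3]), dim = gs)
  nvox <- prod(gs)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- array(-1000 + stats::rnorm(nvox, 0, 5), dim = gs)
    ct[body] <- 30 + stats::rnorm(sum(body), 0, 8)
    ct[bed_arr] <- 150
    tum_c <- body_c + off[i, ]
    tum <- ellipsoid(tum_c, radii[i, ])
    ct[tum] <- 50 + stats::rnorm(sum(tum), 0, texture_sd[i])
    mask <- array(0L, dim = gs); mask[tum] <- 1L

    endpoints <- lapply(eps, function(e) {
      t_ev <- ev_time[e, i]; t_c <- cens[e, i]
      list(time_months = min(t_ev, t_c), event = as.integer(t_ev <= t_c))
    })
    names(endpoints) <- eps

    clin <- list(age = age[i], sex = sex[i], t_stage = t_stage[i],
                 n_stage = n_stage[i], hpv = hpv[i], chemo = chemo[i])
    clin[which(miss[, i])] <- NA

    records[[i]] <- structure(list(
      patient_id = sprintf("P%04d", i),
      ct = ct, gtvp_mask = mask, spacing = sp,
      clinical = clin, endpoints = endpoints,
      persistent_disease = persistent[i],
      latent_risk = risk[i],
      truth = list(volume_mm3 = vol[i], texture_sd = texture_sd[i])
    ), class = "patient_record")
  }
  structure(records, class = "hn_cohort", config = config)
}

#' Dichotomize a time-to-event endpoint at a horizon
#'
#' Applies the 2-year labelling rules: an event on or before the horizon is
#' positive; event-free follow-up past the horizon is negative; censoring
#' before the horizon is excluded as lost to follow-up; a same-day event
#' (time 0) is excluded as ambiguous; patients with persistent disease are
#' excluded from the locoregional-control endpoint.
#'
#' @param time_months Nonnegative follow-up time in months.
#' @param event 1 if the event was observed, 0 if censored.
#' @param persistent 1 if the patient has persistent disease.
#' @param endpoint One of `"OS"`, `"LRC"`, `"FFDM"`.
#' @param horizon Dichotomization horizon in months (default 24).
#' @return A list with `label` in `positive`/`negative`/`excluded` and, when
#'   excluded, a nonempty `exclusion_reason`.
#' @export
dichotomize_endpoint <- function(time_months, event, persistent = 0,
                                 endpoint = c("OS", "LRC", "FFDM"),
                                 horizon = 24) {
  endpoint <- match.arg(endpoint)
  if (!is.numeric(time_months) || is.na(time_months) || time_months < 0)
    stop("time_months must be a nonnegative number", call. = FALSE)
  lab <- function(label, reason = NULL)
    list(endpoint = endpoint, label = label, exclusion_reason = reason)
  if (isTRUE(persistent == 1) && endpoint == "LRC")
    return(lab("excluded", "persistent disease"))
  if (event == 1 && time_months == 0)
    return(lab("excluded", "ambiguous"))
  if (event == 1 && time_months <= horizon) return(lab("positive"))
  if (time_months >= horizon || event == 1) return(lab("negative"))
  lab("excluded", "lost to follow-up")
}

#' Endpoint labels for a whole cohort
#'
#' @param cohort An `hn_cohort`.
#' @param endpoint One of `"OS"`, `"LRC"`, `"FFDM"`.
#' @param horizon Horizon in months.
#' @return A data frame with `patient_id`, `endpoint`, `label`,
#'   `exclusion_reason`.
#' @export
cohort_labels <- function(cohort, endpoint = c("OS", "LRC", "FFDM"),
                          horizon = 24) {
  endpoint <- match.arg(endpoint)
  rows <- lapply(cohort, function(r) {
    e <- r$endpoints[[endpoint]]
    d <- dichotomize_endpoint(e$time_months, e$event, r$persistent_disease,
                              endpoint, horizon)
    data.frame(patient_id = r$patient_id, endpoint = endpoint,
               label = d$label,
               exclusion_reason = d$exclusion_reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinical covariate table of a cohort
#' @param cohort An `hn_cohort`.
#' @return Data frame with columns `patient_id`, `age`, `sex`, `t_stage`,
#'   `n_stage`, `hpv`, `chemo` (missing values as `NA`).
#' @export
cohort_clinical_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    cl <- r$clinical
    data.frame(patient_id = r$patient_id,
               age = cl$age %||% NA_real_, sex = cl$sex %||% NA_integer_,
               t_stage = cl$t_stage %||% NA_integer_,
               n_stage = cl$n_stage %||% NA_integer_,
               hpv = cl$hpv %||% NA_character_,
               chemo = cl$chemo %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Time-to-event endpoint table of a cohort
#' @param cohort An `hn_cohort`.
#' @return Long data frame with columns `patient_id`, `endpoint`,
#'   `time_months`, `event`, `persistent`.
#' @export
cohort_endpoint_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    do.call(rbind, lapply(names(r$endpoints), function(e) {
      data.frame(patient_id = r$patient_id, endpoint = e,
                 time_months = r$endpoints[[e]]$time_months,
                 event = r$endpoints[[e]]$event,
                 persistent = r$persistent_disease,
                 stringsAsFactors = FALSE)
    }))
  }))
}
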