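# Synthetic study cohort: virtual patients with ground-truth cup poses,
# three observers reading every film twice, and per-method measurement
# records produced by projection -> landmark extraction -> observer noise ->
# method formula, mirroring the design of the clinical comparison the
# package emulates (71 patients, 3 observers, 2 intra-observer sessions).

#' Cohort configuration
#'
#' Defaults reproduce the study-shaped world: 71 patients, cup anteversion
#' truncated-normal with mean 19.4 deg inside (12.6, 27.8), cup outer
#' diameter 46-60 mm with mode 50 mm, 28 mm heads, three observers, two
#' sessions, 0.5 mm landmark jitter.
#'
#' @param n_patients number of virtual patients (>= 2).
#' @param anteversion_mean_deg,anteversion_sd_deg,anteversion_range_deg
#'   truncated-normal truth distribution of radiographic anteversion.
#' @param inclination_mean_deg,inclination_sd_deg truth distribution of
#'   inclination (truncated to (25, 65)).
#' @param cup_diameter_range_mm,cup_diameter_mode_mm triangular distribution
#'   of the cup outer diameter, rounded to the even 2-mm shell sizes.
#' @param head_diameter_mm prosthetic-head diameter, mm.
#' @param pelvic_tilt_sd_deg,pelvic_rotation_sd_deg per-film pelvic nuisance
#'   rotations (standardized protocol: small).
#' @param n_observers,n_sessions_intra study design counts.
#' @param landmark_sd_mm,observer_bias_mm observer noise model (see
#'   [observer_model()]).
#' @param reference_points boundary points digitized per curve by the
#'   edge-detection reference.
#' @param seed integer; every random draw derives deterministically from it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 71,
                          anteversion_mean_deg = 19.4,
                          anteversion_sd_deg = 3.5,
                          anteversion_range_deg = c(12.6, 27.8),
                          inclination_mean_deg = 45,
                          inclination_sd_deg = 5,
                          cup_diameter_range_mm = c(46, 60),
                          cup_diameter_mode_mm = 50,
                          head_diameter_mm = 28,
                          pelvic_tilt_sd_deg = 2,
                          pelvic_rotation_sd_deg = 2,
                          n_observers = 3,
                          n_sessions_intra = 2,
                          landmark_sd_mm = 0.5,
                          observer_bias_mm = 0.2,
                          reference_points = 12,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              anteversion_mean_deg = anteversion_mean_deg,
              anteversion_sd_deg = anteversion_sd_deg,
              anteversion_range_deg = as.numeric(anteversion_range_deg),
              inclination_mean_deg = inclination_mean_deg,
              inclination_sd_deg = inclination_sd_deg,
              cup_diameter_range_mm = as.numeric(cup_diameter_range_mm),
              cup_diameter_mode_mm = cup_diameter_mode_mm,
              head_diameter_mm = head_diameter_mm,
              pelvic_tilt_sd_deg = pelvic_tilt_sd_deg,
              pelvic_rotation_sd_deg = pelvic_rotation_sd_deg,
              n_observers = as.integer(n_observers),
              n_sessions_intra = as.integer(n_sessions_intra),
              landmark_sd_mm = landmark_sd_mm,
              observer_bias_mm = observer_bias_mm,
              reference_points = as.integer(reference_points),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  rg <- cfg$anteversion_range_deg
  if (length(rg) != 2 || rg[1] >= rg[2]) {
    stop("anteversion_range_deg must be an increasing pair", call. = FALSE)
  }
  m <- cfg$anteversion_mean_deg; s <- cfg$anteversion_sd_deg
  if (s < 0 || cfg$inclination_sd_deg < 0 || cfg$pelvic_tilt_sd_deg < 0 ||
      cfg$pelvic_rotation_sd_deg < 0 || cfg$landmark_sd_mm < 0 ||
      cfg$observer_bias_mm < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (rg[2] < m - 6 * s || rg[1] > m + 6 * s) {
    stop("impossible truncation: anteversion range excludes mean +/- 6 sd",
         call. = FALSE)
  }
  dr <- cfg$cup_diameter_range_mm
  if (length(dr) != 2 || dr[1] >= dr[2] ||
      cfg$cup_diameter_mode_mm < dr[1] || cfg$cup_diameter_mode_mm > dr[2]) {
    stop("cup diameter range/mode are inconsistent", call. = FALSE)
  }
  if (cfg$n_observers < 1 || cfg$n_sessions_intra < 1) {
    stop("need at least one observer and one session", call. = FALSE)
  }
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, range, rng_seed) {
  with_seed(rng_seed, {
    out <- numeric(0)
    guard <- 0
    while (length(out) < n) {
      x <- stats::rnorm(n, mean, sd)
      out <- c(out, x[x >= range[1] & x <= range[2]])
      guard <- guard + 1
      if (guard > 10000) stop("truncated-normal sampling failed", call. = FALSE)
    }
    out[seq_len(n)]
  })
}

rtriangular <- function(n, lo, hi, mode, rng_seed) {
  with_seed(rng_seed, {
    u <- stats::runif(n)
    fc <- (mode - lo) / (hi - lo)
    ifelse(u < fc,
           lo + sqrt(u * (hi - lo) * (mode - lo)),
           hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  })
}

sample_cohort_truth <- function(cfg) {
  n <- cfg$n_patients
  av <- rtrunc_norm(n, cfg$anteversion_mean_deg, cfg$anteversion_sd_deg,
                    cfg$anteversion_range_deg, derive_seed(cfg$seed, 101L))
  incl <- rtrunc_norm(n, cfg$inclination_mean_deg, cfg$inclination_sd_deg,
                      c(25, 65), derive_seed(cfg$seed, 102L))
  # shells come in 2-mm steps; triangular then snap to the nearest even size
  diam <- rtriangular(n, cfg$cup_diameter_range_mm[1], cfg$cup_diameter_range_mm[2],
                      cfg$cup_diameter_mode_mm, derive_seed(cfg$seed, 103L))
  diam <- pmin(cfg$cup_diameter_range_mm[2],
               pmax(cfg$cup_diameter_range_mm[1], 2 * round(diam / 2)))
  tilt <- with_seed(derive_seed(cfg$seed, 104L),
                    stats::rnorm(n, 0, cfg$pelvic_tilt_sd_deg))
  rot <- with_seed(derive_seed(cfg$seed, 105L),
                   stats::rnorm(n, 0, cfg$pelvic_rotation_sd_deg))
  side <- with_seed(derive_seed(cfg$seed, 106L),
                    sample(c("right", "left"), n, replace = TRUE))
  data.frame(patient_id = seq_len(n),
             anteversion_deg = av, inclination_deg = incl,
             cup_diameter_mm = diam, head_diameter_mm = cfg$head_diameter_mm,
             tilt_deg = tilt, rotation_deg = rot, side = side,
             stringsAsFactors = FALSE)
}

# one edge-detection reference reading: jitter the digitized boundary point
# sets with the observer model (shared systematic offset per curve role,
# iid jitter per point), then run the circle fits and the constrained
# ellipse reconstruction
reference_reading <- function(pose, obs, session, patient_id, n_points,
                              head_radius_mm, tilt_deg, rot_deg) {
  sp <- project_silhouette(pose, n_points = n_points,
                           head_radius_mm = head_radius_mm,
                           tilt_deg = tilt_deg, rot_deg = rot_deg)
  jitter_curve <- function(m, role) {
    sdm <- obs$landmark_sd_mm
    bias <- observer_bias_offset(obs, 100L + role)
    jit <- with_seed(
      derive_seed(obs$seed, obs$observer_id, session, patient_id, 900L, role),
      matrix(stats::rnorm(length(m), 0, sdm), nrow(m), ncol(m)))
    sweep(m + jit, 2, -bias)
  }
  rim <- jitter_curve(sp$rim_points, 1L)
  dome <- jitter_curve(sp$dome_points, 2L)
  head <- jitter_curve(sp$head_points, 3L)
  hfit <- fit_circle(head)
  sfit <- fit_circle(dome)
  version_reference(reconstruct_opening_ellipse(hfit, sfit, rim))
}

#' Generate the synthetic study cohort
#'
#' Samples ground-truth poses from the configured distributions and produces
#' one measurement record per patient x method x observer x session, each
#' obtained by projecting the implant, extracting the method's landmarks,
#' corrupting them with the observer's noise model, and applying the
#' published formula. Fully deterministic under the config seed.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_dataset` list: `poses` (truth table, including the
#'   effective radiographic anteversion seen on each tilted film),
#'   `records` (measurement table: `patient_id, method, observer, session,
#'   value_deg, flags`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  truth <- sample_cohort_truth(config)
  lat_beam <- beam_geometry(film = "crosstable_lateral")
  head_r <- config$head_diameter_mm / 2
  observers <- lapply(seq_len(config$n_observers), function(o) {
    observer_model(config$landmark_sd_mm, config$observer_bias_mm,
                   seed = config$seed, observer_id = o)
  })
  ap_methods <- c("liaw", "lewinnek", "widmer", "hassan", "ackland")

  truth$effective_anteversion_deg <- NA_real_
  truth$effective_lateral_deg <- NA_real_
  rows <- vector("list", nrow(truth) * length(METHOD_IDS) *
                   config$n_observers * config$n_sessions_intra)
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    pose <- cup_pose(tr$anteversion_deg, tr$inclination_deg,
                     tr$cup_diameter_mm / 2, side = tr$side)
    ell <- project_rim(pose, tilt_deg = tr$tilt_deg, rot_deg = tr$rotation_deg)
    truth$effective_anteversion_deg[i] <-
      asind(ell$semi_minor_mm / ell$semi_major_mm)
    lat0 <- project_lateral(pose, lat_beam,
                            tilt_deg = tr$tilt_deg, rot_deg = tr$rotation_deg)
    truth$effective_lateral_deg[i] <- lat0$angle_deg
    lms <- lapply(ap_methods, function(m) {
      extract_landmarks(ell, m, head_radius_mm = head_r)
    })
    names(lms) <- ap_methods
    for (obs in observers) {
      for (ses in seq_len(config$n_sessions_intra)) {
        for (m in ap_methods) {
          vr <- measure_version(perturb(lms[[m]], obs, ses, tr$patient_id))
          k <- k + 1L
          rows[[k]] <- data.frame(patient_id = tr$patient_id, method = m,
                                  observer = obs$observer_id, session = ses,
                                  value_deg = vr$value_deg,
                                  flags = flag_string(vr),
                                  stringsAsFactors = FALSE)
        }
        vr <- version_woo_morrey(perturb(lat0, obs, ses, tr$patient_id))
        k <- k + 1L
        rows[[k]] <- data.frame(patient_id = tr$patient_id, method = "woo_morrey",
                                observer = obs$observer_id, session = ses,
                                value_deg = vr$value_deg, flags = "",
                                stringsAsFactors = FALSE)
        vr <- reference_reading(pose, obs, ses, tr$patient_id,
                                config$reference_points, head_r,
                                tr$tilt_deg, tr$rotation_deg)
        k <- k + 1L
        rows[[k]] <- data.frame(patient_id = tr$patient_id, method = "reference",
                                observer = obs$observer_id, session = ses,
                                value_deg = vr$value_deg, flags = "",
                                stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows[seq_len(k)])
  rownames(records) <- NULL
  structure(list(poses = truth, records = records, config = config),
            class = "cohort_dataset")
}

flag_string <- function(vr) {
  if (isFALSE(vr$in_validity_range)) "out_of_range" else ""
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d patients, %d records (%d methods x %d observers x %d sessions), seed %d\n",
              nrow(x$poses), nrow(x$records), length(unique(x$records$method)),
              x$config$n_observers, x$config$n_sessions_intra, x$config$seed))
  invisible(x)
}

#' Write a cohort dataset to disk
#'
#' Emits `cohort_truth.csv`, `records.csv` and a YAML provenance block
#' (`provenance.yaml`) echoing the full configuration.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_path <- file.path(dir, "cohort_truth.csv")
  rec_path <- file.path(dir, "records.csv")
  prov_path <- file.path(dir, "provenance.yaml")
  utils::write.csv(dataset$poses, truth_path, row.names = FALSE)
  utils::write.csv(dataset$records, rec_path, row.names = FALSE)
  prov <- c(unclass(dataset$config),
            list(note = paste("inclination distribution is an assumption:",
                              "the source cohort reports no inclination summary")))
  yaml::write_yaml(prov, prov_path)
  invisible(c(truth = truth_path, records = rec_path, provenance = prov_path))
}

#' Read measurement records written by [write_cohort()]
#' @param path CSV file with the record schema.
#' @return data frame of records.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "method", "observer", "session", "value_deg")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("records file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rec$flags)) rec$flags <- ""
  rec$flags[is.na(rec$flags)] <- ""
  rec
}
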