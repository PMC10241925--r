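#' Specification for a planted-rule synthetic dataset
#'
#' @param n number of subjects.
#' @param d number of feature columns.
#' @param rule ground-truth [representation()] (a single Boolean tree is
#'   accepted) referencing only columns `<= d`.
#' @param label_noise probability of flipping each label, in `[0, 0.5)`.
#' @param target_prevalence optional outcome prevalence to calibrate the
#'   rule's thresholds toward, in `(0, 1)`.
#' @param correlated_blocks optional list of `list(size =, rho =)` blocks;
#'   the first `sum(size)` columns are drawn as equicorrelated Gaussian
#'   blocks, the rest independently.
#' @param seed integer seed.
#' @return list of class `bf_synth_spec`.
#' @export
synthetic_spec <- function(n, d, rule, label_noise = 0,
                           target_prevalence = NULL,
                           correlated_blocks = NULL, seed = 1L) {
  if (inherits(rule, "bf_node")) rule <- representation(rule)
  if (label_noise < 0 || label_noise >= 0.5) stop("label_noise must be in [0, 0.5)")
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    stop("target_prevalence must be in (0, 1)")
  }
  if (!is.null(correlated_blocks)) {
    for (b in correlated_blocks) {
      if (abs(b$rho) >= 1) stop("block correlations must lie in (-1, 1)")
    }
    if (sum(vapply(correlated_blocks, `[[`, numeric(1L), "size")) > d) {
      stop("correlated blocks exceed d columns")
    }
  }
  structure(list(n = as.integer(n), d = as.integer(d), rule = rule,
                 label_noise = label_noise,
                 target_prevalence = target_prevalence,
                 correlated_blocks = correlated_blocks,
                 seed = as.integer(seed)),
            class = "bf_synth_spec")
}

#' Generate a dataset with a planted Boolean ground-truth rule
#'
#' Features are standard Gaussian (optionally in equicorrelated blocks);
#' labels are the rule's output, XOR-ed with Bernoulli(`label_noise`) flips.
#' When a `target_prevalence` is requested, a common offset is added to
#' every comparison threshold of the rule (positively for `>`, negatively
#' for `<`) and tuned by bisection until the empirical prevalence matches
#' within 0.05; a prevalence the rule cannot reach raises an error. The
#' returned ground-truth rule carries the tuned thresholds, so a noise-free
#' dataset is always perfectly classified by its own rule.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [bf_dataset()]) and `rule` (the tuned
#'   ground-truth [representation()]).
#' @export
make_planted_rule <- function(spec) {
  stopifnot(inherits(spec, "bf_synth_spec"))
  chk <- validate_representation(spec$rule, spec$d, max_dim = 100L,
                                 max_depth = 100L, allow_arith = TRUE)
  if (!chk$ok) stop("rule invalid: ", paste(chk$violations, collapse = "; "))
  out <- local_rng(spec$seed, {
    x <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    col0 <- 0L
    for (b in spec$correlated_blocks) {
      s <- b$size
      sigma <- matrix(b$rho, s, s)
      diag(sigma) <- 1
      L <- chol(sigma)
      x[, col0 + seq_len(s)] <- x[, col0 + seq_len(s), drop = FALSE] %*% L
      col0 <- col0 + s
    }
    colnames(x) <- paste0("x", seq_len(spec$d))
    rule <- spec$rule
    if (!is.null(spec$target_prevalence)) {
      rule <- tune_rule_prevalence(rule, x, spec$target_prevalence)
    }
    y_true <- evaluate_representation(rule, x)[, 1L]
    if (!all(y_true %in% c(0, 1))) stop("rule root must be Boolean")
    flips <- stats::rbinom(spec$n, 1L, spec$label_noise)
    y <- as.integer(xor(y_true == 1, flips == 1))
    list(dataset = bf_dataset(x, y), rule = rule)
  })
  out
}

# Add a common offset to all comparison thresholds (+delta for GT, -delta
# for LT) and bisect it toward the target prevalence.
tune_rule_prevalence <- function(rule, x, target) {
  prev_at <- function(delta) {
    mean(evaluate_representation(shift_thresholds(rule, delta), x)[, 1L])
  }
  lo <- -20
  hi <- 20
  if (prev_at(lo) < target || prev_at(hi) > target) {
    # not bracketed by a monotone-decreasing sweep; check the reverse too
    if (!(prev_at(lo) > target && prev_at(hi) < target)) {
      stop(sprintf("target prevalence %.3f unreachable for this rule", target))
    }
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (prev_at(mid) > target) lo <- mid else hi <- mid
  }
  best <- (lo + hi) / 2
  if (abs(prev_at(best) - target) > 0.05) {
    stop(sprintf("target prevalence %.3f unreachable for this rule (closest %.3f)",
                 target, prev_at(best)))
  }
  shift_thresholds(rule, best)
}

shift_thresholds <- function(rep, delta) {
  shift <- function(nd) {
    if (nd$kind == "GT") nd$threshold <- nd$threshold + delta
    if (nd$kind == "LT") nd$threshold <- nd$threshold - delta
    if (length(nd$children)) nd$children <- lapply(nd$children, shift)
    nd
  }
  representation(lapply(rep$trees, shift))
}

#' Label latent encounter trajectories with the resistant-hypertension
#' heuristic
#'
#' A subject is positive for apparent treatment-resistant hypertension if
#' (a) two encounters within any run of five consecutive outpatient
#' encounters show elevated blood pressure (SBP >= 140 or DBP >= 90) while
#' the subject has been on >= 3 antihypertensive classes for >= 30 days, or
#' (b) the subject has been on >= 4 classes for >= 30 days — and negative
#' regardless if a heart-failure / chronic-kidney-disease exclusion precedes
#' the day the criteria are first met.
#'
#' @param trajectories list, one element per subject: a data.frame with
#'   columns `day`, `sbp`, `dbp`, `n_meds` (current antihypertensive
#'   classes), `days_on_3plus`, `days_on_4plus` (days continuously at that
#'   tier as of the encounter), rows in day order.
#' @param exclusion_day numeric vector (one per subject): day of the first
#'   heart-failure/CKD exclusion, `Inf` if none.
#' @return integer 0/1 labels.
#' @export
atrh_heuristic_label <- function(trajectories, exclusion_day = NULL) {
  if (is.null(exclusion_day)) exclusion_day <- rep(Inf, length(trajectories))
  stopifnot(length(exclusion_day) == length(trajectories))
  vapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    req <- c("day", "sbp", "dbp", "n_meds", "days_on_3plus", "days_on_4plus")
    if (!is.data.frame(tr) || !all(req %in% names(tr))) {
      stop("malformed trajectory for subject ", i,
           ": need columns ", paste(req, collapse = ", "))
    }
    if (is.unsorted(tr$day)) stop("trajectory days out of order for subject ", i)
    qual_day <- Inf
    # (b) four or more classes sustained 30 days
    hit_b <- which(tr$days_on_4plus >= 30)
    if (length(hit_b)) qual_day <- tr$day[hit_b[1L]]
    # (a) 2 qualifying encounters within <= 5 consecutive encounters
    q <- (tr$sbp >= 140 | tr$dbp >= 90) & tr$days_on_3plus >= 30
    hits <- which(q)
    if (length(hits) >= 2L) {
      gap_ok <- which(diff(hits) <= 4L)
      if (length(gap_ok)) {
        qual_day <- min(qual_day, tr$day[hits[gap_ok[1L] + 1L]])
      }
    }
    as.integer(is.finite(qual_day) && qual_day < exclusion_day[i])
  }, integer(1L))
}

#' Generate an EHR-like summarized cohort
#'
#' Simulates per-subject latent primary-care trajectories — years of
#' outpatient encounters, an evolving count of antihypertensive medication
#' classes, systolic/diastolic blood pressures responding to severity and
#' treatment, laboratory draws (potassium, calcium, creatinine, and a panel
#' of generic labs), diagnosis codes, and note mentions — then emits the
#' summarized per-subject feature table a phenotyping pipeline would see:
#' encounter counts per medication tier (sum/median/SD/skewness), blood
#' pressure summaries, lab min/max/median/quartiles, diagnosis-code counts,
#' and note-mention counts (~330 columns). Labels come from
#' [atrh_heuristic_label()] applied to the latent trajectories, so the
#' summarized features relate to the outcome only statistically, mimicking
#' the gap between chart review and extracted features; prevalence lands
#' near 10%.
#'
#' @param n number of subjects (>= 100).
#' @param seed integer seed.
#' @return A raw [bf_dataset()] (run [preprocess()] before modelling), with
#'   the latent trajectories attached as attribute `"trajectories"`.
#' @export
make_ehr_like <- function(n = 1200L, seed = 1L) {
  if (n < 100L) stop("need n >= 100 subjects")
  local_rng(seed, build_ehr_cohort(n))
}

build_ehr_cohort <- function(n) {
  skewness <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(0)
    mean((v - mean(v))^3) / s^3
  }
  n_enc <- pmax(6L, stats::rpois(n, 14L))
  severity <- stats::rnorm(n)             # latent hypertension severity
  adherence <- stats::rnorm(n, 0, 0.5)    # latent treatment responsiveness
  pa_latent <- stats::rnorm(n)            # latent mineralocorticoid excess
  trajectories <- vector("list", n)
  exclusion_day <- rep(Inf, n)
  feats <- vector("list", n)

  n_classes <- 11L
  class_names <- c("ACEi", "ARB", "thiazide", "CCB", "beta-blocker",
                   "loop diuretic", "MRA", "alpha-blocker", "vasodilator",
                   "central agent", "renin inhibitor")
  n_labs <- 53L
  lab_names <- c("Potassium", "Calcium", "Creatinine", "Sodium", "Glucose",
                 paste0("Lab", sprintf("%02d", seq_len(n_labs - 5L))))
  lab_mu <- c(4.1, 9.4, 1.0, 139, 98, stats::rnorm(n_labs - 5L, 50, 20))
  lab_sd <- c(0.35, 0.4, 0.25, 2.5, 18, stats::runif(n_labs - 5L, 2, 10))
  lab_load <- c(-0.35, 0.25, 0.15, 0.05, 0.2, stats::rnorm(n_labs - 5L, 0, 0.15))

  for (i in seq_len(n)) {
    k <- n_enc[i]
    days <- sort(sample.int(3650L, k))
    # medication classes ratchet up with severity over time
    base <- severity[i] * 1.1 + adherence[i] + stats::rnorm(1, -0.05, 0.4)
    drift <- (seq_len(k) / k) * pmax(0, severity[i] + stats::rnorm(1, 0.15, 0.3))
    meds <- pmin(6L, pmax(0L, round(base + drift + stats::rnorm(k, 0, 0.35))))
    # enforce monotone-ish regimens: cummax keeps tiers contiguous
    meds <- cummax(meds)
    run_start <- function(tier) {
      on <- meds >= tier
      start <- rep(NA_real_, k)
      cur <- NA_real_
      for (t_ in seq_len(k)) {
        if (on[t_]) {
          if (is.na(cur)) cur <- days[t_]
          start[t_] <- cur
        } else cur <- NA_real_
      }
      ifelse(is.na(start), Inf, start)
    }
    d3 <- days - run_start(3L)
    d4 <- days - run_start(4L)
    d3[!is.finite(d3)] <- 0
    d4[!is.finite(d4)] <- 0
    treatment_effect <- 6 * (1 - exp(-0.5 * meds)) * (1 + 0.3 * adherence[i])
    resistant <- 0.6 * pmax(0, severity[i] - 0.8) + 0.4 * pmax(0, pa_latent[i] - 1)
    sbp <- round(127 + 9 * severity[i] + 10 * resistant - treatment_effect +
                   stats::rnorm(k, 0, 11))
    dbp <- round(0.55 * sbp + stats::rnorm(k, 6, 7))
    trajectories[[i]] <- data.frame(day = days, sbp = sbp, dbp = dbp,
                                    n_meds = meds, days_on_3plus = d3,
                                    days_on_4plus = d4)
    # heart failure / CKD exclusion arises more often with severe disease
    if (stats::runif(1) < plogis(-3 + 0.6 * severity[i])) {
      exclusion_day[i] <- sample.int(3650L, 1L)
    }

    elevated <- sbp >= 140 | dbp >= 90
    tier_counts <- function(cond) {
      v <- as.numeric(cond)
      c(sum = sum(v), median = stats::median(v), sd = ifelse(k > 1, stats::sd(v), 0),
        skew = skewness(v))
    }
    med_cols <- c(
      stats::setNames(tier_counts(meds == 1),
                      paste0("# enc 1 med, ", c("sum", "median", "sd", "skew"))),
      stats::setNames(tier_counts(meds == 2),
                      paste0("# enc 2 meds, ", c("sum", "median", "sd", "skew"))),
      stats::setNames(tier_counts(meds == 3),
                      paste0("# enc 3 meds, ", c("sum", "median", "sd", "skew"))),
      stats::setNames(tier_counts(meds >= 3),
                      paste0("# enc 3+ meds, ", c("sum", "median", "sd", "skew"))),
      stats::setNames(tier_counts(meds >= 4),
                      paste0("# enc 4+ meds, ", c("sum", "median", "sd", "skew"))))
    max_meds <- max(meds)
    days_rx <- vapply(seq_len(n_classes), function(cl) {
      if (cl <= max_meds) sum(diff(days)[meds[-k] >= cl]) else 0
    }, numeric(1L))
    names(days_rx) <- paste0("days Rx ", class_names)
    lab_k <- pmax(2L, stats::rpois(n_labs, 5L))
    lab_cols <- unlist(lapply(seq_len(n_labs), function(l) {
      mu_i <- lab_mu[l] + lab_load[l] * lab_sd[l] * 2 *
        (severity[i] + (l == 1L) * -0.8 * pa_latent[i] + (l == 2L) * 0.6 * pa_latent[i])
      draws <- stats::rnorm(lab_k[l], mu_i, lab_sd[l])
      qs <- stats::quantile(draws, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      stats::setNames(qs[c(1, 5, 3, 2, 4)],
                      paste0(lab_names[l], ", ", c("min", "max", "median", "q1", "q3")))
    }))
    dx_conditions <- c("HTN", "hypokalemia", "heart failure", "CKD",
                       "diabetes", "CAD", "stroke", "OSA", "obesity", "hyperlipidemia")
    dx_rates <- c(2.5 * plogis(severity[i]), 0.3 * plogis(pa_latent[i] - 1),
                  ifelse(is.finite(exclusion_day[i]), 1.5, 0.05),
                  ifelse(is.finite(exclusion_day[i]), 1.0, 0.1),
                  0.5, 0.4, 0.15, 0.3, 0.6, 0.9)
    years <- max(days) / 365
    dx_sum <- stats::rpois(length(dx_rates), dx_rates * years)
    dx_cols <- c(stats::setNames(dx_sum, paste0("dx ", dx_conditions, ", sum")),
                 stats::setNames(dx_sum / years,
                                 paste0("dx ", dx_conditions, ", median/yr")))
    notes <- stats::rpois(2L, c(1.5, 0.8) * plogis(severity[i]) * years)
    feats[[i]] <- c(
      age = round(stats::runif(1, 25, 90)),
      female = stats::rbinom(1, 1, 0.55),
      race_black = stats::rbinom(1, 1, 0.3),
      weight = round(stats::rnorm(1, 85 + 4 * severity[i], 18)),
      bmi = round(stats::rnorm(1, 29 + 1.5 * severity[i], 5), 1),
      `distance, cat` = sample(0:3, 1L),
      `# encounters` = k,
      `SBP, mean` = mean(sbp), `SBP, max` = max(sbp),
      `SBP, median` = stats::median(sbp), `SBP, sd` = stats::sd(sbp),
      `DBP, mean` = mean(dbp), `DBP, max` = max(dbp), `DBP, sd` = stats::sd(dbp),
      `# elevated BP, sum` = sum(elevated),
      `# elevated BP on meds, sum` = sum(elevated & meds >= 1),
      med_cols, days_rx, lab_cols, dx_cols,
      `note HTN mentions, sum` = notes[1L],
      `note resistant mentions, sum` = notes[2L])
  }
  x <- do.call(rbind, feats)
  labels <- atrh_heuristic_label(trajectories, exclusion_day)
  ds <- bf_dataset(x, labels, colnames(x))
  attr(ds, "trajectories") <- trajectories
  attr(ds, "exclusion_day") <- exclusion_day
  ds
}
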