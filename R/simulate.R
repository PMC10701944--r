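## Synthetic longitudinal records with a known risk mechanism. The generator
## is the testbed standing in for a private primary-care database: sparse
## binary concept occurrence, visit structure inside a 1-year lookback, and
## an outcome driven by static concept effects, a recency effect and age.

#' Configuration for the synthetic record generator
#'
#' @param n_persons number of persons (one observation each).
#' @param n_concepts vocabulary size; concept popularity follows a power-law
#'   (rank^-0.6), so low-index concepts are common and the matrix stays
#'   sparse (1-2% density at the defaults).
#' @param outcome_prevalence target marginal outcome rate in (0, 1); the
#'   intercept is solved so the mean true risk hits it.
#' @param visits_per_person Poisson mean of visits in the lookback year.
#' @param concepts_per_visit Poisson mean of concept draws per visit.
#' @param beta named vector of true log-odds effects, names are concept ids
#'   (e.g. `c(C0001 = 1.5)`); effects act on 365-day-window presence.
#' @param recency_boost extra log-odds if any nonzero-beta concept occurs
#'   within `recency_days` of the index date.
#' @param recency_days the recency window (default 30 days).
#' @param age_effect log-odds per unit of age/100.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_persons = 20000L, n_concepts = 1000L,
                       outcome_prevalence = 0.05,
                       visits_per_person = 8, concepts_per_visit = 2,
                       beta = c(C0001 = 1.5, C0002 = 1.2, C0003 = -1.0,
                                C0004 = 1.0, C0005 = -1.2),
                       recency_boost = 0, recency_days = 30L,
                       age_effect = 1, seed = 42L) {
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1)
    stop_arg("outcome_prevalence must lie in (0, 1)")
  if (visits_per_person <= 0 || concepts_per_visit <= 0)
    stop_arg("rates must be positive")
  structure(list(n_persons = as.integer(n_persons),
                 n_concepts = as.integer(n_concepts),
                 outcome_prevalence = outcome_prevalence,
                 visits_per_person = visits_per_person,
                 concepts_per_visit = concepts_per_visit,
                 beta = beta, recency_boost = recency_boost,
                 recency_days = as.integer(recency_days),
                 age_effect = age_effect, seed = as.integer(seed)),
            class = "sim_config")
}

#' Canned configuration: static concept effects only
#'
#' Five planted effects with `|beta| >= 1` on the five most common concepts,
#' no recency effect. Used for parameter-recovery checks.
#' @param n_persons cohort size.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
config_static_signal <- function(n_persons = 20000L, seed = 42L) {
  sim_config(n_persons = n_persons, seed = seed)
}

#' Canned configuration: recency-dominated mechanism
#'
#' Small static effects plus a strong boost when a causal concept occurs
#' within 30 days of index. A temporal model that sees event times can
#' exploit this; a static model restricted to year-level presence cannot.
#' @param n_persons cohort size.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
config_recency_signal <- function(n_persons = 20000L, seed = 42L) {
  sim_config(n_persons = n_persons, outcome_prevalence = 0.10,
             beta = c(C0001 = 0.3, C0002 = 0.3, C0003 = -0.3,
                      C0004 = 0.3, C0005 = -0.3),
             recency_boost = 1.5, age_effect = 0.5, seed = seed)
}

#' Generate synthetic events, cohort and ground truth
#'
#' Per person: an index date in calendar year 2021, age ~ N(65, 10) clipped
#' to \[40, 95\], sex Bernoulli(1/2); visit day-offsets uniform without
#' replacement over the 365 days before index; per visit a Poisson number of
#' concepts drawn by popularity weight. The linear predictor is
#' `b0 + sum(beta_c * present_c) + recency_boost * any(causal within
#' recency_days) + age_effect * age/100`, with `b0` solved by bisection so
#' the mean of `sigmoid(eta)` equals the target prevalence (tolerance 1e-4).
#' The outcome is Bernoulli of that risk.
#'
#' @param config a [sim_config()].
#' @return a `sim_ehr` list: `events` and `cohort` tables in the formats
#'   [read_events()]/[read_cohort()] produce, and `truth` (per-person risk,
#'   `beta`, `recency_boost`, solved intercept `b0`).
#' @export
generate_ehr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  pid <- sprintf("P%06d", seq_len(n))
  concepts <- sprintf("C%04d", seq_len(config$n_concepts))
  if (!all(names(config$beta) %in% concepts))
    stop_arg("beta names must be generated concept ids")
  w <- (seq_len(config$n_concepts))^(-0.6)
  w <- w / sum(w)

  index_date <- as.Date("2021-01-01") + sample.int(365L, n, replace = TRUE) - 1L
  age <- pmin(pmax(round(rnorm(n, 65, 10)), 40), 95)
  sex <- ifelse(runif(n) < 0.5, "female", "male")

  n_vis <- rpois(n, config$visits_per_person)
  causal <- names(config$beta)[config$beta != 0]
  ev_pid <- vector("list", n); ev_cid <- vector("list", n); ev_delta <- vector("list", n)
  pi <- integer(0); pj <- integer(0)
  recency_hit <- logical(n)
  for (i in seq_len(n)) {
    if (n_vis[i] == 0L) next
    days <- sample.int(365L, min(n_vis[i], 365L)) - 1L  # days before index
    cid <- integer(0); dlt <- integer(0)
    for (d in days) {
      k <- rpois(1L, config$concepts_per_visit)
      if (k == 0L) next
      cs <- sample.int(config$n_concepts, min(k, config$n_concepts), prob = w)
      cid <- c(cid, cs); dlt <- c(dlt, rep.int(d, length(cs)))
    }
    if (!length(cid)) next
    ev_pid[[i]] <- rep.int(i, length(cid)); ev_cid[[i]] <- cid; ev_delta[[i]] <- dlt
    pj_i <- unique(cid)
    pi <- c(pi, rep.int(i, length(pj_i))); pj <- c(pj, pj_i)
    hit <- dlt <= config$recency_days & concepts[cid] %in% causal
    recency_hit[i] <- any(hit)
  }
  present <- Matrix::sparseMatrix(i = pi, j = pj, x = 1,
                                  dims = c(n, config$n_concepts))
  bvec <- setNames(numeric(config$n_concepts), concepts)
  bvec[names(config$beta)] <- config$beta
  eta0 <- as.numeric(present %*% bvec) +
    config$recency_boost * recency_hit +
    config$age_effect * age / 100
  b0 <- solve_intercept(eta0, config$outcome_prevalence)
  risk <- sigmoid(b0 + eta0)
  outcome <- rbinom(n, 1L, risk)

  ii <- unlist(ev_pid); cc <- unlist(ev_cid); dd <- unlist(ev_delta)
  events <- data.table::data.table(
    person_id = pid[ii],
    concept_id = concepts[cc],
    event_date = index_date[ii] - dd,
    domain = c("condition", "drug", "procedure")[(cc %% 3L) + 1L])
  data.table::setorder(events, person_id, event_date, concept_id)
  cohort <- data.table::data.table(
    person_id = pid, index_date = index_date, outcome = outcome,
    age_years = as.numeric(age), sex = sex)
  cohort <- validate_cohort(cohort)
  truth <- structure(list(risk = setNames(risk, cohort$observation_id),
                          beta = config$beta,
                          recency_boost = config$recency_boost,
                          b0 = b0,
                          prevalence_target = config$outcome_prevalence),
                     class = "sim_truth")
  structure(list(events = events, cohort = cohort, truth = truth,
                 config = config), class = "sim_ehr")
}

## bisection on the intercept so mean(sigmoid(b0 + eta)) == target
solve_intercept <- function(eta, target, tol = 1e-4) {
  f <- function(b0) mean(sigmoid(b0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop_arg("prevalence target unreachable")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' @export
print.sim_ehr <- function(x, ...) {
  cat(sprintf("<sim_ehr> %d persons, %d events, prevalence %.3f (target %.3f)\n",
              nrow(x$cohort), nrow(x$events), mean(x$cohort$outcome),
              x$config$outcome_prevalence))
  invisible(x)
}

#' AUC of the true risk against realized outcomes
#'
#' The discrimination ceiling for the generated data: no model can beat the
#' generator's own risk, up to sampling noise.
#'
#' @param truth `sim_truth` from [generate_ehr()].
#' @param cohort the matching cohort table.
#' @return AUC in `[0, 1]` (about 0.5 under no signal).
#' @export
oracle_auc <- function(truth, cohort) {
  roc_auc(truth$risk[cohort$observation_id], cohort$outcome)
}

#' Write a simulation to disk in the flat-file formats the readers accept
#' @param sim a `sim_ehr`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- data.table::copy(sim$events)
  ev[, event_date := format(event_date)]
  data.table::fwrite(ev, file.path(dir, "events.csv"))
  co <- sim$cohort[, c("person_id", "index_date", "outcome", "age_years", "sex")]
  co <- data.table::copy(co)
  co[, index_date := format(index_date)]
  data.table::fwrite(co, file.path(dir, "cohort.csv"))
  jsonlite::write_json(
    list(beta = as.list(sim$truth$beta), b0 = sim$truth$b0,
         recency_boost = sim$truth$recency_boost,
         prevalence_target = sim$truth$prevalence_target,
         risk = as.list(sim$truth$risk)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
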