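# Shared in-code fixtures. Everything is generated programmatically.

# tiny hand-written event/cohort files
write_tiny_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ev <- file.path(dir, "events.csv")
  co <- file.path(dir, "cohort.csv")
  writeLines(c("person_id,concept_id,event_date,domain",
               "p1,C1,2021-05-21,condition",
               "p1,C2,2021-06-30,drug",
               "p2,C1,2020-05-01,procedure"), ev)
  writeLines(c("person_id,index_date,outcome,age_years,sex",
               "p1,2021-06-30,1,70,female",
               "p2,2021-06-01,0,60,male",
               "p3,2021-06-01,1,80,female"), co)
  list(events = ev, cohort = co, dir = dir)
}

small_sim <- function(n = 400, seed = 7, ...) {
  generate_ehr(sim_config(n_persons = n, n_concepts = 30,
                          visits_per_person = 4, concepts_per_visit = 2,
                          beta = c(C0001 = 1.5, C0002 = -1), seed = seed, ...))
}

# a hand-built time-major batch (bypasses make_batches) for attention checks
manual_batch <- function(concepts_per_visit, days, static = NULL, y = NULL,
                         n_concepts = NULL) {
  B <- length(concepts_per_visit)
  Tm <- max(vapply(concepts_per_visit, length, integer(1)))
  n_concepts <- n_concepts %||% max(unlist(concepts_per_visit), 1)
  mask <- matrix(FALSE, B, Tm); dmat <- matrix(0, B, Tm)
  is_null <- matrix(FALSE, B, Tm)
  ii <- integer(0); jj <- integer(0)
  for (b in seq_len(B)) {
    L <- length(concepts_per_visit[[b]])
    mask[b, seq_len(L)] <- TRUE
    dmat[b, seq_len(L)] <- days[[b]]
    for (t in seq_len(L)) {
      cs <- concepts_per_visit[[b]][[t]]
      ii <- c(ii, rep.int((t - 1L) * B + b, length(cs)))
      jj <- c(jj, cs)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(B * Tm, n_concepts))
  static <- static %||% cbind(age = rep(0.7, B), sex = rep(1, B))
  list(ids = paste0("o", seq_len(B)), B = B, T = Tm, S = S, mask = mask,
       days = dmat, is_null = is_null, static = static,
       y = y %||% rep(c(0, 1), length.out = B), age_max = 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ns <- asNamespace("ehrattn")

expect_rel_equal <- function(a, b, tol) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
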