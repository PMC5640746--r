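# In-code fixtures shared across test files.

make_roster <- function(n, types = "other", network_id = "n1",
                        participated = TRUE) {
  data.frame(service_id = sprintf("s%03d", seq_len(n)),
             network_id = network_id,
             service_type = rep_len(types, n),
             participated = rep_len(participated, n))
}

make_tie <- function(reporter, alter, kind = "referral_sent",
                     frequency = "sometimes", network_id = "n1") {
  data.frame(network_id = network_id, reporter_id = reporter,
             alter_id = alter, relation_kind = kind, frequency = frequency)
}

# random binary directed adjacency (no self-loops)
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# a small complete patient row set with constant outcomes
make_patients <- function(n = 4, network_id = "n1", item = 4L) {
  x <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                  network_id = network_id,
                  recruitment_service_type = "psychiatric_ward")
  for (k in 1:31) x[[sprintf("acss_%02d", k)]] <- item
  x$six_employment <- 1L; x$six_accommodation <- 2L
  x$six_family <- 1L; x$six_friends <- 0L
  x$age <- 45L; x$sex <- "male"; x$honos <- 10L
  x$diagnosis <- "mood"
  x$n_outpatient <- 1L; x$n_social <- 0L; x$n_residential <- 1L
  x
}
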