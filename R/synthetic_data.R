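# Synthetic-study generator: 19 referral networks of 11-115 services with a
# realistic type mix, ordinal tie surveys with tunable density / homophily /
# centralization dials, and clustered patients (8 recruitment services x 10
# patients per network) whose continuity and social-integration outcomes
# carry planted network effects, patient-covariate effects and a network
# random intercept. Everything downstream is testable against the planted
# truth.

#' Simulation configuration
#'
#' Returns the default study configuration, optionally overridden by named
#' arguments. Defaults emulate the descriptive statistics of a 19-network
#' national mental-health reform survey: network sizes 11..115 (mean near
#' 52), the published service-type mix, 52\% service participation, tie
#' density near 0.49 with mild type heterophily and a boosted hub, 80
#' patients per network sampled as 8 recruitment clusters of 10, continuity
#' scores with mean 115.6 and a small network-level variance share, and a
#' SIX latent tuned to mean 3.1.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class \code{carenets_config}.
#' @section Fields:
#' \describe{
#'   \item{n_networks}{19}
#'   \item{size_range}{c(11, 115); sizes drawn lognormal within the range}
#'   \item{type_mix}{probability per service type (sums to 1)}
#'   \item{tie_baseline}{baseline tie probability per ordered pair (0.53)}
#'   \item{within_type_mult}{multiplier on the tie probability for same-type
#'     pairs; <1 plants heterophily, >1 homophily (0.5)}
#'   \item{hub_boost}{multiplier on ties pointing at the designated hub
#'     node; >1 plants in-degree centralization (1.8)}
#'   \item{p_often}{probability a present tie is rated often vs sometimes
#'     (0.5)}
#'   \item{p_organizational}{rate of additional organizational-only tie
#'     records, parsed but excluded from clinical networks (0.1)}
#'   \item{participation_rate}{0.52}
#'   \item{n_clusters, cluster_size}{recruitment design: 8 services x 10
#'     patients per network}
#'   \item{continuity}{list: intercept 115.6; \code{effects}, a named vector
#'     of standardized coefficients on network metrics (default none);
#'     coef_age 0.05, coef_sex_male 0, coef_honos -0.3; ri_sd 2.5 and
#'     resid_sd 13.9 (network-level variance share ~3\%)}
#'   \item{six}{list: \code{effects} (named latent log-odds coefficients on
#'     standardized network metrics, default none); coef_age 0, coef_sex_male
#'     0, coef_honos -0.05; ri_sd 0.6 (latent ICC ~10\%); thresholds tuned
#'     for mean 3.1}
#'   \item{incomplete_rate}{probability a patient record has a missing ACSS
#'     item (default 0)}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_networks = 19L,
    size_range = c(11L, 115L),
    type_mix = c(primary_care = 0.128, community_mental_health = 0.108,
                 crisis_outreach = 0.100, rehabilitation = 0.116,
                 social_services = 0.209, psychiatric_ward = 0.171,
                 sheltered_housing = 0.102, nursing_home = 0.035,
                 other = 0.031),
    tie_baseline = 0.53,
    within_type_mult = 0.5,
    hub_boost = 1.8,
    p_often = 0.5,
    p_organizational = 0.1,
    participation_rate = 0.52,
    n_clusters = 8L,
    cluster_size = 10L,
    continuity = list(intercept = 115.6, effects = numeric(0),
                      coef_age = 0.05, coef_sex_male = 0,
                      coef_honos = -0.3, ri_sd = 2.5, resid_sd = 13.9),
    six = list(effects = numeric(0), coef_age = 0, coef_sex_male = 0,
               coef_honos = -0.05, ri_sd = 0.6,
               thresholds = c(-3.1276, -1.9276, -0.7276,
                              0.4724, 1.6724, 2.8724)),
    incomplete_rate = 0
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    if (nm %in% c("continuity", "six"))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_networks >= 1, cfg$size_range[1] >= 3,
            cfg$size_range[2] >= cfg$size_range[1])
  if (abs(sum(cfg$type_mix) - 1) > 1e-6)
    stop("type_mix must sum to 1", call. = FALSE)
  probs <- c(cfg$tie_baseline, cfg$p_often, cfg$p_organizational,
             cfg$participation_rate, cfg$incomplete_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be within [0, 1]", call. = FALSE)
  if (cfg$within_type_mult < 0 || cfg$hub_boost < 0)
    stop("multipliers must be non-negative", call. = FALSE)
  structure(cfg, class = "carenets_config")
}

# Deterministic per-(seed, index, stage) substream seed, kept below 2^31.
substream <- function(seed, index, stage = 0L) {
  as.integer((as.double(seed) * 48271 + index * 12347 + stage * 101) %%
               2147483629)
}

#' Generate one network's roster and tie survey
#'
#' Node types are drawn from the configured type mix; each observable
#' ordered pair (reporter or alter participating) receives a directed
#' ordinal clinical tie independently with probability
#' \code{tie_baseline x within_type_mult^[same type] x hub_boost^[alter is
#' hub]} (capped at 1), rated often with probability \code{p_often} and
#' sometimes otherwise. Ties are emitted in survey form: by the sender as a
#' referral_sent or info_exchange, or by the receiver as a
#' referral_received (the only channel when the sender did not participate).
#' Additional organizational records are emitted at rate
#' \code{p_organizational}. Node 1 is the designated hub and always
#' participates.
#'
#' @param config A \code{\link{sim_config}}.
#' @param network_index 1-based network number (names the network).
#' @param seed Integer; the network uses a substream derived from
#'   (seed, network_index).
#' @return List with \code{roster} and \code{ties} data frames, valid
#'   \code{\link{validate_roster}} / \code{\link{validate_ties}} input.
#' @export
generate_network <- function(config, network_index, seed) {
  cfg <- validate_config(config)
  set.seed(substream(seed, network_index, 1L))
  nid <- sprintf("net%02d", network_index)

  lo <- cfg$size_range[1]; hi <- cfg$size_range[2]
  n <- if (lo == hi) lo else {
    s <- round(stats::rlnorm(1, meanlog = log(44), sdlog = 0.6))
    as.integer(min(max(s, lo), hi))
  }
  types <- sample(names(cfg$type_mix), n, replace = TRUE, prob = cfg$type_mix)
  participated <- stats::runif(n) < cfg$participation_rate
  participated[1] <- TRUE                      # hub responds
  if (sum(participated) < 3L) participated[1:3] <- TRUE
  roster <- data.frame(service_id = sprintf("%s_s%03d", nid, seq_len(n)),
                       network_id = nid, service_type = types,
                       participated = participated)

  ids <- roster$service_id
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  observable <- participated[pairs$i] | participated[pairs$j]
  pairs <- pairs[observable, ]
  p <- rep(cfg$tie_baseline, nrow(pairs))
  p <- p * ifelse(types[pairs$i] == types[pairs$j], cfg$within_type_mult, 1)
  p <- p * ifelse(pairs$j == 1L, cfg$hub_boost, 1)
  p <- pmin(p, 1)
  present <- stats::runif(nrow(pairs)) < p
  tp <- pairs[present, ]
  freq <- ifelse(stats::runif(nrow(tp)) < cfg$p_often, "often", "sometimes")

  # survey encoding: sender report when possible, receiver report otherwise
  # (and in a third of dyads where both responded, to exercise the reversal)
  i_part <- participated[tp$i]
  j_part <- participated[tp$j]
  u <- stats::runif(nrow(tp))
  by_receiver <- (!i_part & j_part) | (i_part & j_part & u < 1 / 3)
  kind <- ifelse(by_receiver, "referral_received",
                 ifelse(u < 2 / 3, "referral_sent", "info_exchange"))
  reporter <- ifelse(by_receiver, ids[tp$j], ids[tp$i])
  alter <- ifelse(by_receiver, ids[tp$i], ids[tp$j])
  ties <- data.frame(network_id = nid, reporter_id = reporter,
                     alter_id = alter, relation_kind = kind,
                     frequency = freq)

  if (cfg$p_organizational > 0) {
    op <- pairs[participated[pairs$i] &
                  stats::runif(nrow(pairs)) < cfg$p_organizational, ]
    if (nrow(op) > 0L)
      ties <- rbind(ties, data.frame(
        network_id = nid, reporter_id = ids[op$i], alter_id = ids[op$j],
        relation_kind = "organizational",
        frequency = sample(c("sometimes", "often"), nrow(op),
                           replace = TRUE)))
  }
  rownames(ties) <- NULL
  list(roster = roster, ties = ties)
}

# z-score network metric columns across networks (each network once);
# errors if a planted-effect metric is missing or undefined somewhere.
standardize_metrics <- function(metrics, effect_names) {
  z <- list()
  for (nm in effect_names) {
    v <- metrics[[nm]]
    if (is.null(v)) stop("unknown metric in effects: ", nm, call. = FALSE)
    if (anyNA(v))
      stop("metric ", nm, " undefined for some network(s); ",
           "cannot plant an effect on it", call. = FALSE)
    s <- stats::sd(v)
    if (s == 0) stop("metric ", nm, " constant across networks", call. = FALSE)
    z[[nm]] <- (v - mean(v)) / s
  }
  z
}

# Distribute an integer total t over components with the given caps by
# repeatedly incrementing a random non-full component.
allocate_components <- function(t, caps) {
  comp <- integer(length(caps))
  for (step in seq_len(t)) {
    open <- which(comp < caps)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    comp[pick] <- comp[pick] + 1L
  }
  comp
}

#' Generate clustered patient records with planted network effects
#'
#' Per network, \code{n_clusters} recruitment services x \code{cluster_size}
#' patients. The continuity latent mean is
#' \code{intercept + sigma_tot * sum(beta_k * z(metric_k)) + covariate terms
#' + network random intercept}, with Gaussian residual; \code{sigma_tot =
#' sqrt(ri_sd^2 + resid_sd^2)}, so \code{effects} are standardized
#' coefficients. The latent total is spread over the 31 ACSS items by
#' bounded rounding (items differ by at most 1 and sum exactly to the
#' rounded total). The SIX total is drawn from an ordered-threshold logistic
#' model on an analogous latent (so \code{six$effects} are latent log-odds
#' coefficients on standardized metrics) and then allocated to the four
#' components within their 2/2/1/1 caps.
#'
#' @param config A \code{\link{sim_config}}.
#' @param metrics The \code{metrics} data frame of a
#'   \code{\link{metrics_table}} over the generated networks (needed only
#'   when effects are planted; may be NULL otherwise).
#' @param seed Integer substream seed.
#' @return A patient data frame passing \code{\link{validate_patients}}.
#' @export
generate_patients <- function(config, metrics = NULL, seed = 1L) {
  cfg <- validate_config(config)
  set.seed(substream(seed, 0L, 2L))
  nets <- if (!is.null(metrics)) as.character(metrics$network_id)
  else sprintf("net%02d", seq_len(cfg$n_networks))
  n_net <- length(nets)
  z_cont <- standardize_metrics(metrics, names(cfg$continuity$effects))
  z_six <- standardize_metrics(metrics, names(cfg$six$effects))

  n_per <- cfg$n_clusters * cfg$cluster_size
  total_n <- n_net * n_per
  net_idx <- rep(seq_len(n_net), each = n_per)

  # recruitment design: primary care + community mental health, two
  # crisis/outreach, two psychiatric wards, one long-term residential,
  # one social or rehabilitation service
  cluster_types <- function() {
    base <- c("primary_care", "community_mental_health",
              "crisis_outreach", "crisis_outreach",
              "psychiatric_ward", "psychiatric_ward",
              sample(c("sheltered_housing", "nursing_home"), 1L),
              sample(c("social_services", "rehabilitation"), 1L))
    rep_len(base, cfg$n_clusters)
  }
  recruit <- as.vector(vapply(seq_len(n_net), function(i)
    rep(cluster_types(), each = cfg$cluster_size), character(n_per)))

  age <- pmin(pmax(round(stats::rnorm(total_n, 45.7, 12.6)), 18), 90)
  sex <- ifelse(stats::runif(total_n) < 0.48, "male", "female")
  honos <- pmin(pmax(round(stats::rnorm(total_n, 12.5, 6.5)), 0), 48)
  diagnosis <- sample(DIAGNOSES, total_n, replace = TRUE,
                      prob = c(0.286, 0.254, 0.174, 0.151, 0.065, 0.070))

  cc <- cfg$continuity
  sigma_tot <- sqrt(cc$ri_sd^2 + cc$resid_sd^2)
  u_cont <- stats::rnorm(n_net, 0, cc$ri_sd)
  eta <- cc$intercept + u_cont[net_idx] +
    cc$coef_age * (age - 45.7) +
    cc$coef_sex_male * (sex == "male") +
    cc$coef_honos * (honos - 12.5)
  for (nm in names(z_cont))
    eta <- eta + sigma_tot * cc$effects[[nm]] * z_cont[[nm]][net_idx]
  latent <- eta + stats::rnorm(total_n, 0, cc$resid_sd)
  total <- pmin(pmax(round(latent), 31L), 155L)

  # spread the total over 31 items: all items q or q+1, sum exact
  items <- matrix(0L, total_n, 31L)
  q <- total %/% 31L
  r <- total - 31L * q
  for (i in seq_len(total_n)) {
    row <- rep(q[i], 31L)
    if (r[i] > 0L) row[sample.int(31L, r[i])] <- q[i] + 1L
    items[i, ] <- row
  }

  sx <- cfg$six
  u_six <- stats::rnorm(n_net, 0, sx$ri_sd)
  eta6 <- u_six[net_idx] +
    sx$coef_age * (age - 45.7) +
    sx$coef_sex_male * (sex == "male") +
    sx$coef_honos * (honos - 12.5)
  for (nm in names(z_six))
    eta6 <- eta6 + sx$effects[[nm]] * z_six[[nm]][net_idx]
  l6 <- eta6 + stats::rlogis(total_n)
  six_tot <- rowSums(outer(l6, sx$thresholds, ">"))
  caps <- c(2L, 2L, 1L, 1L)
  six_comp <- t(vapply(six_tot, allocate_components, integer(4), caps = caps))

  patients <- data.frame(
    patient_id = sprintf("p%05d", seq_len(total_n)),
    network_id = nets[net_idx],
    recruitment_service_type = recruit)
  for (k in 1:31) patients[[acss_cols()[k]]] <- items[, k]
  patients$six_employment <- six_comp[, 1]
  patients$six_accommodation <- six_comp[, 2]
  patients$six_family <- six_comp[, 3]
  patients$six_friends <- six_comp[, 4]
  patients$age <- age
  patients$sex <- sex
  patients$honos <- honos
  patients$diagnosis <- diagnosis
  patients$n_outpatient <- stats::rpois(total_n, 1.5)
  patients$n_social <- stats::rpois(total_n, 0.7)
  patients$n_residential <- stats::rpois(total_n, 0.7)

  if (cfg$incomplete_rate > 0) {
    hit <- which(stats::runif(total_n) < cfg$incomplete_rate)
    for (i in hit)
      patients[i, acss_cols()[sample.int(31L, 1L)]] <- NA_integer_
  }
  patients
}

#' Generate a complete synthetic study
#'
#' Rosters and tie surveys for all configured networks, clinical networks
#' built under the main rule (sometimes-or-often, participants only), their
#' metrics, and clustered patient records with any configured planted
#' effects. Deterministic given \code{seed}. If \code{dir} is given, writes
#' \code{services.csv}, \code{ties.csv} and \code{patients.csv} in the
#' canonical dialect.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer master seed; all stages use substreams derived from
#'   it.
#' @param dir Optional output directory.
#' @return List with \code{services}, \code{ties}, \code{patients},
#'   \code{networks} (list of \code{carenets_network} built under the main
#'   rule) and \code{metrics} (a \code{\link{metrics_table}}).
#' @export
#' @examples
#' study <- generate_study(sim_config(n_networks = 2,
#'   size_range = c(8, 12), n_clusters = 2, cluster_size = 5), seed = 1)
#' nrow(study$patients)
generate_study <- function(config = sim_config(), seed = 1L, dir = NULL) {
  cfg <- validate_config(config)
  nets <- lapply(seq_len(cfg$n_networks), function(i)
    generate_network(cfg, i, seed))
  services <- do.call(rbind, lapply(nets, `[[`, "roster"))
  ties <- do.call(rbind, lapply(nets, `[[`, "ties"))
  rownames(services) <- rownames(ties) <- NULL

  built <- lapply(nets, function(nw)
    build_network(nw$roster, validate_ties(nw$ties, nw$roster)))
  mt <- metrics_table(built)
  patients <- generate_patients(cfg, mt$metrics, seed = seed)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_roster(services, file.path(dir, "services.csv"))
    write_ties(ties, file.path(dir, "ties.csv"))
    write_patients(patients, file.path(dir, "patients.csv"))
  }
  list(services = services, ties = ties, patients = patients,
       networks = built, metrics = mt)
}
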