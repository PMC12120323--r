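# Independent brute-force oracles, coded deliberately differently from the
# package implementations they cross-check.

# simple-ratio index by a literal per-period scan over every pair
oracle_sri <- function(groups, individuals = sort(unique(groups$transmitter_id))) {
  m <- length(individuals)
  sri <- matrix(0, m, m, dimnames = list(individuals, individuals))
  by_period <- split(groups[c("transmitter_id", "receiver_id")],
                     groups$sampling_period)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      A <- individuals[a]; B <- individuals[b]
      x <- y_ab <- y_a <- y_b <- 0
      for (gp in by_period) {
        seen_a <- A %in% gp$transmitter_id
        seen_b <- B %in% gp$transmitter_id
        if (!seen_a && !seen_b) next
        if (seen_a && seen_b) {
          recs_a <- gp$receiver_id[gp$transmitter_id == A]
          recs_b <- gp$receiver_id[gp$transmitter_id == B]
          if (length(intersect(recs_a, recs_b)) > 0) x <- x + 1 else y_ab <- y_ab + 1
        } else if (seen_a) y_a <- y_a + 1 else y_b <- y_b + 1
      }
      denom <- x + y_ab + y_a + y_b
      sri[a, b] <- sri[b, a] <- if (denom > 0) x / denom else 0
    }
  }
  sri
}

# weighted categorical assortativity by explicit edge loops
oracle_assortativity <- function(w, labels) {
  classes <- sort(unique(labels))
  k <- length(classes)
  e <- matrix(0, k, k)
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    e[match(labels[i], classes), match(labels[j], classes)] <-
      e[match(labels[i], classes), match(labels[j], classes)] + w[i, j]
  }
  e <- e / sum(e)
  a <- rowSums(e); b <- colSums(e)
  (sum(diag(e)) - sum(a * b)) / (1 - sum(a * b))
}

# one-factor PERMANOVA pseudo-F straight from the distance matrix
# (within-group sum over pairs), independent of the Gower-matrix route
oracle_permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  lv <- unique(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  df1 <- length(lv) - 1
  df2 <- n - length(lv)
  (ss_between / df1) / (ss_within / df2)
}

# brute-force movement edge recount: double loop over consecutive detections
oracle_movement_edges <- function(det, window_hours = 24) {
  det <- det[order(det$timestamp), , drop = FALSE]
  tab <- list()
  if (nrow(det) >= 2) {
    for (i in seq_len(nrow(det) - 1)) {
      j <- i + 1
      dt <- as.numeric(det$timestamp[j]) - as.numeric(det$timestamp[i])
      if (det$receiver_id[i] != det$receiver_id[j] && dt <= window_hours * 3600) {
        key <- paste(sort(c(det$receiver_id[i], det$receiver_id[j])),
                     collapse = "|")
        tab[[key]] <- (tab[[key]] %||% 0) + 1
      }
    }
  }
  if (length(tab) == 0) {
    return(data.frame(from = character(), to = character(),
                      weight = integer()))
  }
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    weight = as.integer(unlist(tab)))
  out[order(out$from, out$to), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all n! orderings of 1:n (rows), for exact enumeration at tiny n
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# random co-detection schedule for SRI tests
random_schedule <- function(n_ind, n_periods, n_receivers = 4, p_obs = 0.3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  rows <- expand.grid(transmitter_id = ids,
                      sampling_period = seq_len(n_periods),
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < p_obs, , drop = FALSE]
  if (nrow(rows) == 0) return(random_schedule(n_ind, n_periods, n_receivers,
                                              min(1, p_obs * 2)))
  rows$receiver_id <- sprintf("R%d", sample.int(n_receivers, nrow(rows),
                                                replace = TRUE))
  tibble::as_tibble(rows[, c("sampling_period", "receiver_id",
                             "transmitter_id")])
}

# assemble a bay_dataset directly from hand-written tables
toy_dataset <- function(detections, tags, receivers, min_days = 1) {
  suppressMessages(filter_dataset(detections, tags, receivers,
                                  min_days = min_days))
}

toy_receivers <- function(n = 3, zone = "marine") {
  tibble::tibble(
    receiver_id = sprintf("R%d", seq_len(n)),
    longitude = seq(25.60, 26.10, length.out = n),
    latitude = -33.9,
    depth_m = 10,
    zone = zone,
    active_start = as.Date("2014-01-01"),
    active_end = as.Date("2016-12-31")
  ) |> validate_receivers()
}

toy_tags <- function(ids, species = "C_taurus", life_stage = "adult",
                     tag_date = as.Date("2014-01-01"),
                     study_end = as.Date("2016-12-31")) {
  tibble::tibble(
    transmitter_id = ids,
    species = species,
    life_stage = life_stage,
    length_mm = 2000,
    tag_date = tag_date,
    tag_region = "coastal",
    battery_expiry = as.Date("2020-01-01"),
    recapture_date = as.Date(NA),
    last_outside_detection = as.Date(NA)
  ) |> validate_tags(study_end = study_end)
}

# timestamps in the analysis timezone
ts <- function(x) as.POSIXct(x, tz = "Etc/GMT-2")

# small fast scenario used across tests
quick_scenario <- function(seed = 1, assortment = 0, amplitude = c(0, 0),
                           base_prob = c(0.3, 0.3), peak = c(7L, 7L),
                           n_per_species = 6L,
                           span = as.Date(c("2014-06-01", "2015-05-31"))) {
  sp <- tibble::tibble(
    species = c("C_taurus", "C_carcharias"),
    base_prob = base_prob, peak_month = peak, amplitude = amplitude,
    battery_life_days = 2000L, tag_region = "coastal",
    w_west = 0.4, w_central = 0.3, w_east = 0.3
  )
  sim_scenario(
    n_receivers = 6, species_params = sp,
    cohort = tibble::tibble(species = c("C_taurus", "C_carcharias"),
                            life_stage = "adult", n = n_per_species),
    study_span = span, assortment_strength = assortment,
    recapture_hazard = 0, seed = seed
  )
}
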