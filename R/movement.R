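#' Movement network for one individual
#'
#' Receivers are nodes; an edge joins two distinct receivers each time they
#' host consecutive detections of the individual separated by at most
#' `window` hours (the default 24-h rule). Edges are undirected by default
#' and weighted by the number of such transitions; consecutive detections at
#' the same receiver add nothing. The alternative `"calendar"` rule instead
#' links every pair of distinct receivers the individual visited within one
#' calendar day.
#'
#' @param dataset A `bay_dataset`.
#' @param individual Transmitter ID of a retained individual.
#' @param window Time window in hours (consecutive rule only).
#' @param rule `"consecutive"` (default) or `"calendar"`.
#' @param directed Keep transition direction? Default `FALSE` (undirected).
#' @return A `movement_network`: list with `edges` (tibble `from`, `to`,
#'   `weight`), `nodes` (all deployed receiver IDs), `visited`,
#'   `node_weights` (detection counts per visited receiver) and `owner`.
#' @export
build_movement_network <- function(dataset, individual, window = 24,
                                   rule = c("consecutive", "calendar"),
                                   directed = FALSE) {
  stopifnot(inherits(dataset, "bay_dataset"))
  rule <- match.arg(rule)
  det <- dataset$detections %>%
    filter(.data$transmitter_id == individual) %>%
    arrange(.data$timestamp)
  if (nrow(det) == 0) abort(sprintf("no detections for '%s'", individual))

  if (rule == "consecutive") {
    rec <- det$receiver_id
    dt_ok <- diff(as.numeric(det$timestamp)) <= window * 3600
    move <- rec[-1] != rec[-length(rec)] & dt_ok
    edges <- tibble(from = rec[-length(rec)][move], to = rec[-1][move])
  } else {
    edges <- det %>%
      distinct(.data$date, .data$receiver_id) %>%
      inner_join(det %>% distinct(.data$date, .data$receiver_id),
                 by = "date", relationship = "many-to-many",
                 suffix = c("_a", "_b")) %>%
      filter(.data$receiver_id_a < .data$receiver_id_b) %>%
      select(from = "receiver_id_a", to = "receiver_id_b")
  }
  if (!directed && nrow(edges) > 0) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  edges <- edges %>% count(.data$from, .data$to, name = "weight")
  node_weights <- det %>% count(.data$receiver_id, name = "n_detections")
  out <- list(
    edges = edges,
    nodes = dataset$receivers$receiver_id,
    visited = sort(unique(det$receiver_id)),
    node_weights = node_weights,
    owner = individual,
    directed = directed,
    rule = rule,
    window = window
  )
  class(out) <- "movement_network"
  out
}

#' @export
print.movement_network <- function(x, ...) {
  cat(sprintf("<movement_network> owner %s: %d/%d receivers visited, %d edges (%s, %s)\n",
              x$owner, length(x$visited), length(x$nodes), nrow(x$edges),
              x$rule, if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Node and edge density of a movement network
#'
#' Node density is the share of deployed receivers the individual used; edge
#' density is the share of all unordered receiver pairs in the deployed
#' array that appear as edges. Using the full deployed array as the
#' denominator keeps densities comparable across individuals.
#'
#' @param net A `movement_network`.
#' @param array_size Number of deployed receivers (defaults to the array
#'   recorded in the network).
#' @return Tibble with `owner`, `n_nodes`, `n_edges`, `node_density`,
#'   `edge_density`.
#' @export
network_densities <- function(net, array_size = length(net$nodes)) {
  stopifnot(inherits(net, "movement_network"))
  if (array_size < 2) abort("array_size must be >= 2")
  if (length(net$visited) > array_size) {
    abort("visited receivers exceed the deployed array size")
  }
  avail_edges <- if (net$directed) array_size * (array_size - 1) else
    choose(array_size, 2)
  tibble(
    owner = net$owner,
    n_nodes = length(net$visited),
    n_edges = nrow(net$edges),
    node_density = length(net$visited) / array_size,
    edge_density = nrow(net$edges) / avail_edges
  )
}

#' Per-individual movement networks and their densities
#'
#' @param dataset A `bay_dataset`.
#' @inheritParams build_movement_network
#' @return A list with `networks` (named list of `movement_network`) and
#'   `densities` (tibble with species and life stage joined on, ready for
#'   [compare_groups()]).
#' @export
movement_networks <- function(dataset, window = 24,
                              rule = c("consecutive", "calendar"),
                              directed = FALSE) {
  stopifnot(inherits(dataset, "bay_dataset"))
  rule <- match.arg(rule)
  ids <- dataset$tags$transmitter_id
  nets <- lapply(ids, function(id) {
    build_movement_network(dataset, id, window = window, rule = rule,
                           directed = directed)
  })
  names(nets) <- ids
  dens <- purrr::map(nets, network_densities) %>% list_rbind() %>%
    left_join(dataset$tags %>%
                select(owner = "transmitter_id", "species", "life_stage"),
              by = "owner")
  list(networks = nets, densities = dens)
}

#' Aggregate movement networks by group
#'
#' Sums edge weights across the individuals of each group (for plotting
#' space use by species or life stage) and renormalizes pooled per-receiver
#' detection counts into node proportions for node sizing.
#'
#' @param nets Named list of `movement_network` objects.
#' @param by Grouping vector aligned with `nets` (e.g. species labels).
#' @return Named list of aggregated `movement_network` objects; each has a
#'   `node_weights` tibble with an added `proportion` column.
#' @export
aggregate_networks <- function(nets, by) {
  stopifnot(length(nets) == length(by))
  groups <- split(seq_along(nets), by)
  out <- lapply(names(groups), function(g) {
    sub <- nets[groups[[g]]]
    edges <- purrr::map(sub, "edges") %>% list_rbind() %>%
      group_by(.data$from, .data$to) %>%
      summarise(weight = sum(.data$weight), .groups = "drop")
    nw <- purrr::map(sub, "node_weights") %>% list_rbind() %>%
      group_by(.data$receiver_id) %>%
      summarise(n_detections = sum(.data$n_detections), .groups = "drop") %>%
      mutate(proportion = .data$n_detections / sum(.data$n_detections))
    agg <- list(
      edges = edges,
      nodes = sub[[1]]$nodes,
      visited = sort(unique(unlist(purrr::map(sub, "visited")))),
      node_weights = nw,
      owner = g,
      directed = sub[[1]]$directed,
      rule = sub[[1]]$rule,
      window = sub[[1]]$window
    )
    class(agg) <- "movement_network"
    agg
  })
  names(out) <- names(groups)
  out
}

#' Per-receiver detection-proportion profiles
#'
#' Each retained individual's detections are tallied per deployed receiver
#' and normalized to sum to one; receivers never visited get zero. These
#' simplex profiles are the response for the spatial-segregation PERMANOVA.
#'
#' @param dataset A `bay_dataset`.
#' @return Wide tibble: `transmitter_id` plus one numeric column per
#'   deployed receiver, rows summing to 1.
#' @export
receiver_use_profiles <- function(dataset) {
  stopifnot(inherits(dataset, "bay_dataset"))
  recs <- dataset$receivers$receiver_id
  counts <- dataset$detections %>%
    count(.data$transmitter_id, .data$receiver_id)
  if (any(!dataset$tags$transmitter_id %in% counts$transmitter_id)) {
    abort("retained individual with zero detections: filtering is inconsistent")
  }
  wide <- counts %>%
    group_by(.data$transmitter_id) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    pivot_wider(names_from = "receiver_id", values_from = "prop",
                values_fill = 0)
  for (r in setdiff(recs, names(wide))) wide[[r]] <- 0
  wide %>%
    select("transmitter_id", all_of(recs)) %>%
    arrange(.data$transmitter_id)
}
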