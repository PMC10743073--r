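# Reaction pathways as graphs of stationary points: minima connected through
# transition states, named routes, per-step barriers, bottlenecks, reaction
# energies, and Eyring transition-state-theory rate/barrier conversion.

# CODATA values
.KB_J_PER_K <- 1.380649e-23
.H_J_S <- 6.62607015e-34
.R_KCAL_PER_MOL_K <- 8.31446261815324 / 4184

#' Build a validated reaction pathway graph
#'
#' Stationary points are minima or transition states with energies in
#' kcal/mol relative to a declared reference species. Every transition state
#' must connect exactly two minima (two edges), and every named route must
#' alternate minimum, TS, minimum, ... along existing edges.
#'
#' @param points Data frame with columns `label`, `kind` (`"minimum"` or
#'   `"transition_state"`), `energy` (kcal/mol); optional columns `ambiguous`
#'   (logical provenance flag) and `note`.
#' @param edges Data frame (or 2-column matrix) with columns `minimum`, `ts`.
#' @param routes Named list of character vectors of labels.
#' @param reference Label of the zero-energy reference species.
#' @return A `pathway_graph`.
#' @export
build_pathway <- function(points, edges, routes = list(), reference = NULL) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "kind", "energy") %in% names(points)))
  if (!"ambiguous" %in% names(points)) points$ambiguous <- FALSE
  if (!"note" %in% names(points)) points$note <- ""
  points$label <- as.character(points$label)
  if (anyDuplicated(points$label))
    stop("duplicate stationary-point label(s): ",
         paste(unique(points$label[duplicated(points$label)]), collapse = ", "),
         call. = FALSE)
  if (!all(points$kind %in% c("minimum", "transition_state")))
    stop("kind must be 'minimum' or 'transition_state'", call. = FALSE)
  if (!all(is.finite(points$energy)))
    stop("energies must be finite", call. = FALSE)

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) stop("edges must have two columns (minimum, ts)",
                              call. = FALSE)
  names(edges) <- c("minimum", "ts")
  edges[] <- lapply(edges, as.character)
  kind_of <- stats::setNames(points$kind, points$label)
  for (col in names(edges)) {
    unknown <- setdiff(edges[[col]], points$label)
    if (length(unknown))
      stop("edge references unknown label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(edges)) {
    if (!all(kind_of[edges$minimum] == "minimum"))
      stop("edge 'minimum' column must name minima", call. = FALSE)
    if (!all(kind_of[edges$ts] == "transition_state"))
      stop("edge 'ts' column must name transition states", call. = FALSE)
  }
  ts_labels <- points$label[points$kind == "transition_state"]
  deg <- table(factor(edges$ts, levels = ts_labels))
  bad <- names(deg)[deg != 2L]
  if (length(bad))
    stop("transition state(s) not connecting exactly two minima: ",
         paste(bad, collapse = ", "), call. = FALSE)

  if (length(routes) && (is.null(names(routes)) || any(names(routes) == "")))
    stop("routes must be a named list", call. = FALSE)
  edge_key <- paste(edges$minimum, edges$ts, sep = "\r")
  for (rn in names(routes)) {
    rt <- as.character(routes[[rn]])
    unknown <- setdiff(rt, points$label)
    if (length(unknown))
      stop("route '", rn, "' references unknown label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (length(rt) < 3L || length(rt) %% 2L == 0L)
      stop("route '", rn, "' must be an odd-length minimum/TS alternation",
           call. = FALSE)
    want <- rep(c("minimum", "transition_state"), length.out = length(rt))
    if (!all(kind_of[rt] == want))
      stop("route '", rn, "' does not alternate minimum, TS, minimum, ...",
           call. = FALSE)
    for (i in seq(1L, length(rt) - 2L, by = 2L)) {
      ts <- rt[i + 1L]
      for (m in rt[c(i, i + 2L)]) {
        if (!(paste(m, ts, sep = "\r") %in% edge_key))
          stop("route '", rn, "' uses missing edge (", m, ", ", ts, ")",
               call. = FALSE)
      }
    }
    routes[[rn]] <- rt
  }

  if (is.null(reference)) reference <- points$label[points$kind == "minimum"][1L]
  if (!reference %in% points$label)
    stop("unknown reference label '", reference, "'", call. = FALSE)
  structure(list(points = points, edges = edges, routes = routes,
                 reference = reference),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d stationary points (%d TS), %d edges, %d routes\n",
              nrow(x$points), sum(x$points$kind == "transition_state"),
              nrow(x$edges), length(x$routes)))
  if (length(x$routes))
    cat("routes:", paste(names(x$routes), collapse = ", "), "\n")
  invisible(x)
}

energy_of <- function(graph, label) {
  i <- match(as.character(label), graph$points$label)
  if (is.na(i)) stop("unknown stationary point '", label, "'", call. = FALSE)
  graph$points$energy[i]
}

#' Energy of one stationary point relative to another
#'
#' @param graph A `pathway_graph`.
#' @param label,reference_label Stationary-point labels.
#' @return `E(label) - E(reference_label)` in kcal/mol.
#' @export
relative_energy <- function(graph, label,
                            reference_label = graph$reference) {
  energy_of(graph, label) - energy_of(graph, reference_label)
}

#' Barrier of a single elementary step
#'
#' `E(ts) - E(from_minimum)` for an existing (minimum, TS) edge. A negative
#' barrier (TS below its minimum) raises a validation warning.
#'
#' @param graph A `pathway_graph`.
#' @param from_minimum,ts Labels of the step's starting minimum and TS.
#' @return Barrier in kcal/mol.
#' @export
step_barrier <- function(graph, from_minimum, ts) {
  hit <- graph$edges$minimum == from_minimum & graph$edges$ts == ts
  if (!any(hit))
    stop("no edge (", from_minimum, ", ", ts, ") in the pathway graph",
         call. = FALSE)
  b <- energy_of(graph, ts) - energy_of(graph, from_minimum)
  if (b < 0)
    warning("transition state ", ts, " lies ", format(-b),
            " kcal/mol below minimum ", from_minimum, call. = FALSE)
  b
}

#' Bottleneck of a named route
#'
#' The largest single-step barrier along the route (TS energy minus the
#' preceding minimum), with its transition state. Ties go to the earliest
#' step.
#'
#' @param graph A `pathway_graph`.
#' @param route_name Name of a route in the graph.
#' @return List with `ts` (label) and `barrier` (kcal/mol).
#' @export
route_bottleneck <- function(graph, route_name) {
  rt <- graph$routes[[route_name]]
  if (is.null(rt)) stop("unknown route '", route_name, "'", call. = FALSE)
  starts <- seq(1L, length(rt) - 2L, by = 2L)
  barriers <- vapply(starts, function(i)
    energy_of(graph, rt[i + 1L]) - energy_of(graph, rt[i]), numeric(1))
  best <- which.max(barriers)          # which.max takes the earliest tie
  list(ts = rt[starts[best] + 1L], barrier = barriers[best])
}

#' Reaction energy between two stationary points
#'
#' `E(end) - E(start)`; negative means exothermic.
#'
#' @param graph A `pathway_graph`.
#' @param start_label,end_label Stationary-point labels.
#' @return Energy difference in kcal/mol.
#' @export
reaction_energy <- function(graph, start_label, end_label) {
  energy_of(graph, end_label) - energy_of(graph, start_label)
}

#' Energetic span of a route
#'
#' The largest `E(TS_j) - E(min_i)` over pairs with the minimum at or before
#' the TS along the route -- the effective barrier when intermediates
#' equilibrate. Provided for comparison; the step-barrier convention is used
#' everywhere else in this package.
#'
#' @inheritParams route_bottleneck
#' @return List with `ts`, `minimum` and `span` (kcal/mol).
#' @export
energetic_span <- function(graph, route_name) {
  rt <- graph$routes[[route_name]]
  if (is.null(rt)) stop("unknown route '", route_name, "'", call. = FALSE)
  mins <- rt[seq(1L, length(rt), by = 2L)]
  tss <- rt[seq(2L, length(rt) - 1L, by = 2L)]
  best <- list(span = -Inf, ts = NA_character_, minimum = NA_character_)
  for (j in seq_along(tss)) {
    for (i in seq_len(j)) {
      s <- energy_of(graph, tss[j]) - energy_of(graph, mins[i])
      if (s > best$span) best <- list(span = s, ts = tss[j], minimum = mins[i])
    }
  }
  best[c("ts", "minimum", "span")]
}

#' Transition-state-theory specification
#'
#' @param temperature Temperature in kelvin (> 0).
#' @param transmission_coefficient Dimensionless, in (0, 1].
#' @return An `eyring_spec`.
#' @export
eyring_spec <- function(temperature = 298.15, transmission_coefficient = 1) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  if (!is.finite(transmission_coefficient) || transmission_coefficient <= 0 ||
      transmission_coefficient > 1)
    stop("transmission coefficient must lie in (0, 1]", call. = FALSE)
  structure(list(temperature = temperature,
                 transmission_coefficient = transmission_coefficient),
            class = "eyring_spec")
}

#' Eyring conversion between rate constants and activation barriers
#'
#' `eyring_barrier_from_rate()` inverts the Eyring equation,
#' `k = kappa * (kB T / h) * exp(-dG / (R T))`, returning
#' `dG = R T ln(kappa kB T / (h k))` in kcal/mol;
#' `eyring_rate_from_barrier()` is its exact inverse. Physical constants are
#' CODATA values.
#'
#' @param rate First-order rate constant in 1/s (> 0).
#' @param barrier Activation free energy in kcal/mol.
#' @param spec An [eyring_spec()].
#' @return Barrier in kcal/mol, or rate in 1/s.
#' @export
eyring_barrier_from_rate <- function(rate, spec = eyring_spec()) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive", call. = FALSE)
  T <- spec$temperature
  pre <- spec$transmission_coefficient * .KB_J_PER_K * T / .H_J_S
  .R_KCAL_PER_MOL_K * T * log(pre / rate)
}

#' @rdname eyring_barrier_from_rate
#' @export
eyring_rate_from_barrier <- function(barrier, spec = eyring_spec()) {
  if (!is.finite(barrier)) stop("barrier must be finite", call. = FALSE)
  T <- spec$temperature
  pre <- spec$transmission_coefficient * .KB_J_PER_K * T / .H_J_S
  pre * exp(-barrier / (.R_KCAL_PER_MOL_K * T))
}

#' Cumulative energy profile of a route as a table
#'
#' @param graph A `pathway_graph`.
#' @param route_name Optional route; defaults to all points in storage order.
#' @return Data frame with columns `label`, `kind`, `energy` (kcal/mol,
#'   relative to the graph reference).
#' @export
profile_table <- function(graph, route_name = NULL) {
  labels <- if (is.null(route_name)) graph$points$label
            else {
              rt <- graph$routes[[route_name]]
              if (is.null(rt)) stop("unknown route '", route_name, "'",
                                    call. = FALSE)
              rt
            }
  idx <- match(labels, graph$points$label)
  data.frame(label = labels, kind = graph$points$kind[idx],
             energy = graph$points$energy[idx] - energy_of(graph, graph$reference),
             stringsAsFactors = FALSE)
}

#' Read/write a pathway graph as JSON
#'
#' The JSON layout is `{reference, points: [{label, kind, energy,
#' ambiguous?, note?}], edges: [[minimum, ts], ...], routes: {name:
#' [labels]}}`.
#'
#' @param path JSON file path.
#' @return `read_pathway_json()`: a `pathway_graph`.
#' @export
read_pathway_json <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  edges <- j$edges
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  build_pathway(points = j$points,
                edges = as.data.frame(edges, stringsAsFactors = FALSE),
                routes = as.list(j$routes),
                reference = j$reference)
}

#' @rdname read_pathway_json
#' @param graph A `pathway_graph`.
#' @export
write_pathway_json <- function(graph, path) {
  jsonlite::write_json(
    list(reference = graph$reference,
         points = graph$points,
         edges = unname(as.matrix(graph$edges)),
         routes = graph$routes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
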