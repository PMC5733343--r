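# Directed degradation-pathway graphs and fate overlays.

TRANSFORMATION_TYPES <- c("DEGLYCOSYLATION", "C_RING_CLEAVAGE",
                          "DEHYDROXYLATION", "REDUCTION", "OXIDATION",
                          "BETA_OXIDATION", "ALPHA_OXIDATION", "HYDROLYSIS",
                          "OTHER")

NODE_ROLES <- c("PRECURSOR", "INTERMEDIATE", "TERMINAL_METABOLITE",
                "UNKNOWN")

#' Load a degradation-pathway graph
#'
#' Reads a pathway fixture: a tab-delimited file with `node` records (name,
#' optional library peak id, formula, and an `expected_undetectable` flag
#' for compounds known to ionize too weakly to be observed) and `edge`
#' records (from, to, transformation type). The graph is validated to be a
#' DAG with no dangling edges. Three fixtures are bundled: `"naringenin"`,
#' `"catechin"` and `"salicyl"`.
#'
#' @param name Bundled fixture name, or a path to a fixture file.
#' @return A list of class `pathway_graph` with data frames `nodes` (`name`,
#'   `peak_id`, `formula`, `expected_undetectable`) and `edges` (`from`,
#'   `to`, `type`).
#' @export
#' @examples
#' pw <- load_pathway("catechin")
#' nrow(pw$edges)
load_pathway <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "pathways", paste0(name, ".tsv"),
                package = "gutfate")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("pathway fixture not found: ", name, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(fields, `[[`, character(1), 1L)
  bad <- setdiff(unique(kind), c("node", "edge"))
  if (length(bad)) {
    stop("unknown record type(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(fields[kind == "node"], function(f) {
    if (length(f) < 5) stop("node record with too few fields", call. = FALSE)
    data.frame(name = f[2],
               peak_id = suppressWarnings(as.integer(f[3])),
               formula = f[4],
               expected_undetectable = as.logical(f[5]),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(fields[kind == "edge"], function(f) {
    if (length(f) < 4) stop("edge record with too few fields", call. = FALSE)
    data.frame(from = f[2], to = f[3], type = f[4], stringsAsFactors = FALSE)
  }))
  if (is.null(nodes) || nrow(nodes) == 0L) {
    stop("pathway has no nodes: ", path, call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "),
         call. = FALSE)
  }
  dangling <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(dangling)) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(edges$type), TRANSFORMATION_TYPES)
  if (length(bad_type)) {
    stop("unknown transformation type(s): ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  graph <- structure(list(nodes = nodes, edges = edges),
                     class = "pathway_graph")
  if (.has_cycle(graph)) {
    stop("pathway graph contains a cycle: ", path, call. = FALSE)
  }
  graph
}

# Kahn's algorithm; TRUE if a cycle remains.
.has_cycle <- function(graph) {
  nodes <- graph$nodes$name
  edges <- graph$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  queue <- nodes[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    removed <- removed + 1L
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  removed < length(nodes)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

# Node role from its fate label and out-degree. A decreasing or
# fast-metabolized compound is a precursor; a triaged intermediate is an
# intermediate; an increasing compound is a terminal metabolite only when
# the pathway itself declares it an endpoint (no outgoing edges) -- an
# increasing interior node is still being converted onward, so it takes the
# intermediate role. Everything else (unchanged, undetected) is unknown.
node_role <- function(fate, out_degree) {
  if (is.na(fate)) return("UNKNOWN")
  switch(fate,
    DECREASING = , FAST_METABOLIZED = "PRECURSOR",
    INTERMEDIATE = "INTERMEDIATE",
    INCREASING = if (out_degree > 0L) "INTERMEDIATE" else
      "TERMINAL_METABOLITE",
    "UNKNOWN")
}

#' Consistency verdict for one pathway edge
#'
#' An edge u -> v is `CONSISTENT` when the upstream role is `PRECURSOR` or
#' `INTERMEDIATE` and the downstream role is `INTERMEDIATE` or
#' `TERMINAL_METABOLITE` (material flows in the drawn direction);
#' `INCONSISTENT` when a `TERMINAL_METABOLITE` — a compound whose fate says
#' it only accumulates — is drawn as feeding a formed product; and
#' `UNDETERMINED` when either role is `UNKNOWN`.
#'
#' @param role_from,role_to Node roles (see `NODE_ROLES`).
#' @return `"CONSISTENT"`, `"INCONSISTENT"` or `"UNDETERMINED"`.
#' @export
edge_verdict <- function(role_from, role_to) {
  role_from <- match.arg(role_from, NODE_ROLES)
  role_to <- match.arg(role_to, NODE_ROLES)
  if (role_from == "UNKNOWN" || role_to == "UNKNOWN") return("UNDETERMINED")
  if (role_from %in% c("PRECURSOR", "INTERMEDIATE") &&
      role_to %in% c("INTERMEDIATE", "TERMINAL_METABOLITE")) {
    return("CONSISTENT")
  }
  if (role_from == "TERMINAL_METABOLITE" &&
      role_to %in% c("INTERMEDIATE", "TERMINAL_METABOLITE")) {
    return("INCONSISTENT")
  }
  "UNDETERMINED"
}

#' Overlay triage fates on a pathway graph
#'
#' Assigns each node a role from its fate label and scores every edge for
#' consistency with the drawn direction of transformation. Compounds flagged
#' `expected_undetectable` (weak ionization) that have no fate stay
#' `UNKNOWN`, so their edges are `UNDETERMINED` rather than inconsistent.
#' Fates naming compounds absent from the graph produce a warning, not an
#' error.
#'
#' @param graph A [load_pathway()] graph.
#' @param fates Named character vector: compound name -> fate label (one of
#'   the triage labels). Compounds without an entry are treated as
#'   undetected.
#' @return A list of class `pathway_overlay`: `nodes` (with `detected`,
#'   `fate`, `role`), `edges` (with `verdict`), and `coverage` (detected
#'   nodes / total nodes).
#' @export
#' @examples
#' pw <- load_pathway("salicyl")
#' ov <- overlay_fates(pw, c(salicin = "DECREASING",
#'                           saligenin = "INCREASING"))
#' ov$coverage
overlay_fates <- function(graph, fates) {
  stopifnot(inherits(graph, "pathway_graph"))
  fates <- fates[!is.na(fates)]
  if (length(fates)) {
    stray <- setdiff(names(fates), graph$nodes$name)
    if (length(stray)) {
      warning("fate(s) for compound(s) not in graph: ",
              paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  nodes <- graph$nodes
  out_deg <- vapply(nodes$name,
                    function(n) sum(graph$edges$from == n), integer(1))
  nodes$fate <- ifelse(nodes$name %in% names(fates),
                       unname(fates[nodes$name]), NA_character_)
  nodes$detected <- !is.na(nodes$fate) &
    !nodes$fate %in% c("INSUFFICIENT_DATA")
  nodes$role <- vapply(seq_len(nrow(nodes)), function(i) {
    if (!nodes$detected[i]) "UNKNOWN" else
      node_role(nodes$fate[i], out_deg[i])
  }, character(1))
  edges <- graph$edges
  role_of <- stats::setNames(nodes$role, nodes$name)
  edges$verdict <- vapply(seq_len(nrow(edges)), function(i) {
    edge_verdict(role_of[[edges$from[i]]], role_of[[edges$to[i]]])
  }, character(1))
  structure(list(nodes = nodes, edges = edges,
                 coverage = sum(nodes$detected) / nrow(nodes)),
            class = "pathway_overlay")
}

#' @export
print.pathway_overlay <- function(x, ...) {
  cat(sprintf("<pathway_overlay> coverage %.2f (%d/%d nodes detected)\n",
              x$coverage, sum(x$nodes$detected), nrow(x$nodes)))
  print(table(verdict = x$edges$verdict))
  invisible(x)
}

#' Summarize a pathway overlay
#'
#' @param overlay A [overlay_fates()] result.
#' @return A list: `n_nodes`, `n_detected`, `n_undetected`, `coverage`,
#'   `roles` (counts per role), `verdicts` (counts per verdict),
#'   `consistent_fraction` and `inconsistent_fraction` (of determined
#'   edges; `NaN` when no edge is determined).
#' @export
coverage_report <- function(overlay) {
  stopifnot(inherits(overlay, "pathway_overlay"))
  nodes <- overlay$nodes; edges <- overlay$edges
  roles <- table(factor(nodes$role, levels = NODE_ROLES))
  verdicts <- table(factor(edges$verdict,
                           levels = c("CONSISTENT", "INCONSISTENT",
                                      "UNDETERMINED")))
  determined <- sum(verdicts[c("CONSISTENT", "INCONSISTENT")])
  list(n_nodes = nrow(nodes), n_detected = sum(nodes$detected),
       n_undetected = sum(!nodes$detected), coverage = overlay$coverage,
       roles = roles, verdicts = verdicts,
       consistent_fraction = unname(verdicts[["CONSISTENT"]] / determined),
       inconsistent_fraction = unname(verdicts[["INCONSISTENT"]] /
                                        determined))
}

#' Compound fates from triage and annotation reports
#'
#' Links triage fates to compound names via the annotation report so they
#' can be overlaid on a pathway: for each annotated compound the fate of its
#' best-ranked feature at the requested concentration is used. Features
#' flagged as abiotic are excluded from the mapping (their change is not
#' microbial).
#'
#' @param fates A [run_triage()] report.
#' @param annotations An [annotate_features()] report.
#' @param concentration Which extract concentration's fates to use.
#' @param drop_abiotic Exclude abiotic-flagged features (default `TRUE`).
#' @return Named character vector, compound name -> fate label.
#' @export
compound_fates <- function(fates, annotations, concentration,
                           drop_abiotic = TRUE) {
  f <- fates[fates$concentration == concentration, ]
  if (drop_abiotic) f <- f[!(f$abiotic_flag %in% TRUE), ]
  top <- annotations[annotations$rank == 1L, ]
  merged <- merge(top, f, by = "feature_id")
  merged <- merged[order(merged$name, abs(merged$delta_ppm)), ]
  merged <- merged[!duplicated(merged$name), ]
  stats::setNames(merged$label, merged$name)
}
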