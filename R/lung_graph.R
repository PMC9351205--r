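# The 10-node anatomical lung graph: a fixed airway tree (trachea root ->
# carina -> main bronchi -> lobes) plus a tumor node attached to its host
# lobe(s).  Topology depends only on tumor lobe membership, never on image
# content.

#' Canonical node roles
#'
#' The ten roles of the lung graph in canonical order: four airway
#' landmarks, five lobes, one tumor.  Feature blocks, neighbor sequences
#' and serialized graphs all use this order.
#'
#' @return character vector of length 10.
#' @export
node_roles <- function() {
  c("ROOT", "CENTER", "LEFT", "RIGHT", "LUL", "LLL", "RUL", "RML", "RLL", "TUMOR")
}

#' Lobe roles (label value 1..5 -> role)
#' @return character vector of length 5.
#' @export
lobe_roles <- function() c("LUL", "LLL", "RUL", "RML", "RLL")

# The fixed anatomical tree.  "Natural" connectivity is resolved as the
# airway anatomy the landmarks trace: trachea root - carina, carina - each
# main bronchus, each bronchus - its lung's lobes.
FIXED_EDGES <- matrix(c("ROOT", "CENTER",
                        "CENTER", "LEFT",
                        "CENTER", "RIGHT",
                        "LEFT", "LUL",
                        "LEFT", "LLL",
                        "RIGHT", "RUL",
                        "RIGHT", "RML",
                        "RIGHT", "RLL"),
                      ncol = 2, byrow = TRUE)

#' Build the lung-graph edge list
#'
#' The fixed 8-edge anatomical tree plus one TUMOR edge per host lobe.
#' Edges are undirected, stored once, each endpoint pair ordered canonically
#' and the list sorted lexicographically by role.
#'
#' @param tumor_lobes nonempty character vector of lobe roles (or integer
#'   labels 1..5) the tumor overlaps.
#' @return `m x 2` character matrix of edges.
#' @export
build_topology <- function(tumor_lobes) {
  if (length(tumor_lobes) == 0) stop("tumor_lobes must be nonempty")
  if (is.numeric(tumor_lobes)) {
    if (!all(tumor_lobes %in% 1:5)) stop("numeric tumor lobes must be in 1..5")
    tumor_lobes <- lobe_roles()[tumor_lobes]
  }
  bad <- setdiff(tumor_lobes, lobe_roles())
  if (length(bad) > 0)
    stop("not lobe roles: ", paste(bad, collapse = ", "))
  tumor_lobes <- unique(tumor_lobes)
  edges <- rbind(FIXED_EDGES, cbind(rep("TUMOR", length(tumor_lobes)), tumor_lobes))
  ord <- match(edges, node_roles())
  dim(ord) <- dim(edges)
  flip <- ord[, 1] > ord[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  ord[flip, ] <- ord[flip, 2:1]
  edges <- edges[order(ord[, 1], ord[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  edges
}

#' Assemble a lung graph
#'
#' @param features named list (role -> length-96 vector) or a 10 x 96
#'   matrix with role rownames; all ten roles must be present.
#' @param tumor_lobes lobe roles (or labels 1..5) hosting the tumor.
#' @param patient_id identifier string.
#' @param label optional binary 5-year outcome (1 = death within 60
#'   months); NA allowed (censored before 60 months, excluded from
#'   classification).
#' @return a `lung_graph`: `nodes` (roles, canonical order), `edges`,
#'   `features` (10 x 96, canonical row order), `patient_id`, `label`,
#'   `tumor_lobes`.
#' @export
build_graph <- function(features, tumor_lobes, patient_id, label = NULL) {
  roles <- node_roles()
  if (is.list(features)) {
    missing_roles <- setdiff(roles, names(features))
    if (length(missing_roles) > 0)
      stop("missing node feature for role: ", paste(missing_roles, collapse = ", "))
    feat <- do.call(rbind, lapply(roles, function(r) as.numeric(features[[r]])))
  } else {
    feat <- as.matrix(features)
    if (is.null(rownames(feat))) {
      if (nrow(feat) != 10) stop("feature matrix must have 10 rows")
      rownames(feat) <- roles
    }
    missing_roles <- setdiff(roles, rownames(feat))
    if (length(missing_roles) > 0)
      stop("missing node feature for role: ", paste(missing_roles, collapse = ", "))
    feat <- feat[roles, , drop = FALSE]
  }
  if (!all(is.finite(feat))) stop("node features must be finite")
  rownames(feat) <- roles
  edges <- build_topology(tumor_lobes)
  if (is.numeric(tumor_lobes)) tumor_lobes <- lobe_roles()[tumor_lobes]
  g <- structure(list(nodes = roles, edges = edges,
                      features = feat, patient_id = patient_id,
                      label = if (is.null(label)) NA_integer_ else as.integer(label),
                      tumor_lobes = unique(tumor_lobes)),
                 class = "lung_graph")
  stopifnot(graph_connected(g))
  g
}

graph_connected <- function(g) {
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  igraph::is_connected(ig) && igraph::vcount(ig) == length(g$nodes)
}

#' @export
print.lung_graph <- function(x, ...) {
  cat(sprintf("<lung_graph> patient %s: 10 nodes, %d edges, tumor in %s, label %s\n",
              x$patient_id, nrow(x$edges), paste(x$tumor_lobes, collapse = "+"),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

# Adjacency as a list: role -> neighbor roles in canonical order.
graph_neighbors <- function(g) {
  roles <- g$nodes
  nb <- stats::setNames(vector("list", length(roles)), roles)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) v[order(match(v, roles))])
}

#' Serialize a lung graph (JSON metadata + TSV feature payload)
#'
#' Writes `<stem>.json` (patient id, label, tumor lobes, edges, node order)
#' and `<stem>.tsv` (one row per role, features at %.17g — lossless for
#' doubles).
#'
#' @param g a `lung_graph`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
serialize_graph <- function(g, stem) {
  jsonlite::write_json(list(patient_id = g$patient_id,
                            label = if (is.na(g$label)) NULL else g$label,
                            tumor_lobes = g$tumor_lobes,
                            nodes = g$nodes,
                            edges = apply(g$edges, 1, identity, simplify = FALSE),
                            feature_dim = ncol(g$features)),
                       paste0(stem, ".json"), auto_unbox = TRUE, null = "null")
  rows <- vapply(g$nodes, function(r)
    paste(c(r, sprintf("%.17g", g$features[r, ])), collapse = "\t"), character(1))
  writeLines(rows, paste0(stem, ".tsv"))
  invisible(stem)
}

#' Deserialize a lung graph written by [serialize_graph]
#'
#' Node rows may appear in any order in the payload; the canonical role
#' order is restored.
#'
#' @param stem path stem.
#' @return a `lung_graph`.
#' @export
deserialize_graph <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(stem, ".tsv"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  roles <- vapply(parts, `[[`, character(1), 1)
  if (!setequal(roles, node_roles()))
    stop("corrupted graph payload: roles ", paste(roles, collapse = ","))
  feat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (anyNA(feat)) stop("corrupted graph payload: non-numeric features")
  rownames(feat) <- roles
  label <- if (is.null(meta$label)) NA_integer_ else as.integer(meta$label)
  build_graph(feat, meta$tumor_lobes, meta$patient_id,
              label = if (is.na(label)) NULL else label)
}
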