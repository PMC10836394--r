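# Job graph of a RELION project, parsed from pipeline.star.
#
# The RELION 4 dialect is confined to this table so a rename in a later
# RELION release is a one-line change.
pipeline_dialect <- list(
  processes = "pipeline_processes",
  nodes = "pipeline_nodes",
  input_edges = "pipeline_input_edges",
  output_edges = "pipeline_output_edges",
  proc_name = "rlnPipeLineProcessName",
  proc_alias = "rlnPipeLineProcessAlias",
  proc_type = "rlnPipeLineProcessTypeLabel",
  proc_status = "rlnPipeLineProcessStatusLabel",
  node_name = "rlnPipeLineNodeName",
  in_from = "rlnPipeLineEdgeFromNode",
  in_proc = "rlnPipeLineEdgeProcess",
  out_proc = "rlnPipeLineEdgeProcess",
  out_to = "rlnPipeLineEdgeToNode",
  job_params = "joboptions_values",
  job_var = "rlnJobOptionVariable",
  job_val = "rlnJobOptionValue"
)

#' Parse a pipeline.star document into a job graph
#'
#' A RELION project is a bipartite graph: jobs (processes) produce data
#' nodes (files) that other jobs consume. Job types and statuses are
#' passed through verbatim, so job types introduced by newer RELION
#' releases are accepted unchanged. The induced job-level graph (job A
#' feeds job B through at least one shared data node) must be acyclic.
#'
#' @param doc a `star_document` read from `pipeline.star`, or a path to
#'   one.
#' @return an object of class `pipeline_graph`: list with `jobs`
#'   (data.frame: name, alias, type, status), `data_nodes` (character) and
#'   `edges` (data.frame: from, to, kind where kind is `"output"` for
#'   job->node and `"input"` for node->job).
#' @export
parse_pipeline <- function(doc) {
  if (is.character(doc)) doc <- read_star(doc)
  stopifnot(inherits(doc, "star_document"))
  d <- pipeline_dialect
  grab <- function(block) {
    tryCatch(get_table(doc, block), relmeta_lookup_error = function(e) NULL)
  }
  procs <- grab(d$processes)
  if (is.null(procs)) {
    relmeta_stop("pipeline document lacks a data_%s block", d$processes,
                 class = "relmeta_structure_error")
  }
  col <- function(tab, lab, default = NULL) {
    if (is.null(tab) || nrow(tab) == 0L) return(character(0))
    if (lab %in% names(tab)) as.character(tab[[lab]])
    else if (!is.null(default)) rep(default, nrow(tab))
    else relmeta_stop("pipeline block lacks label _%s", lab,
                      class = "relmeta_structure_error")
  }
  jobs <- data.frame(
    name = col(procs, d$proc_name),
    alias = col(procs, d$proc_alias, default = "None"),
    type = col(procs, d$proc_type, default = ""),
    status = col(procs, d$proc_status, default = ""),
    stringsAsFactors = FALSE)
  if (anyDuplicated(jobs$name)) {
    relmeta_stop("duplicate job name '%s' in pipeline",
                 jobs$name[duplicated(jobs$name)][1],
                 class = "relmeta_structure_error")
  }
  nodes <- col(grab(d$nodes), d$node_name)
  ie <- grab(d$input_edges)
  oe <- grab(d$output_edges)
  edges <- rbind(
    data.frame(from = col(oe, d$out_proc), to = col(oe, d$out_to),
               kind = rep("output", if (is.null(oe)) 0 else nrow(oe)),
               stringsAsFactors = FALSE),
    data.frame(from = col(ie, d$in_from), to = col(ie, d$in_proc),
               kind = rep("input", if (is.null(ie)) 0 else nrow(ie)),
               stringsAsFactors = FALSE))
  for (i in seq_len(nrow(edges))) {
    jb <- if (edges$kind[i] == "output") edges$from[i] else edges$to[i]
    nd <- if (edges$kind[i] == "output") edges$to[i] else edges$from[i]
    if (!jb %in% jobs$name) {
      relmeta_stop("edge references unknown job '%s'", jb,
                   class = "relmeta_structure_error")
    }
    if (!nd %in% nodes) {
      relmeta_stop("edge references unknown data node '%s'", nd,
                   class = "relmeta_structure_error")
    }
  }
  g <- structure(list(jobs = jobs, data_nodes = nodes, edges = edges),
                 class = "pipeline_graph")
  topological_order(g)  # validates acyclicity of the induced job graph
  g
}

#' @export
print.pipeline_graph <- function(x, ...) {
  cat(sprintf("<pipeline_graph: %d job(s), %d data node(s), %d edge(s)>\n",
              nrow(x$jobs), length(x$data_nodes), nrow(x$edges)))
  invisible(x)
}

#' Induced job-to-job edges
#'
#' Producer/consumer pairs connected through at least one shared data
#' node, deduplicated and ordered by producer then consumer name.
#'
#' @param graph a [parse_pipeline()] result.
#' @return `data.frame` with columns `from`, `to`.
#' @export
job_edges <- function(graph) {
  stopifnot(inherits(graph, "pipeline_graph"))
  out <- graph$edges[graph$edges$kind == "output", c("from", "to")]
  inp <- graph$edges[graph$edges$kind == "input", c("from", "to")]
  m <- merge(out, inp, by.x = "to", by.y = "from")
  pairs <- unique(data.frame(from = m$from, to = m$to.y,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Topological order of the jobs
#'
#' Kahn's algorithm over the induced job graph; ties among ready jobs are
#' broken by job name so the order is deterministic.
#'
#' @param graph a [parse_pipeline()] result.
#' @return character vector of job names, producers before consumers.
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "pipeline_graph"))
  names_ <- graph$jobs$name
  je <- job_edges(graph)
  indeg <- stats::setNames(integer(length(names_)), names_)
  adj <- stats::setNames(vector("list", length(names_)), names_)
  for (i in seq_len(nrow(je))) {
    indeg[[je$to[i]]] <- indeg[[je$to[i]]] + 1L
    adj[[je$from[i]]] <- c(adj[[je$from[i]]], je$to[i])
  }
  ready <- sort(names_[indeg == 0L])
  order_ <- character(0)
  while (length(ready)) {
    j <- ready[1]
    ready <- ready[-1]
    order_ <- c(order_, j)
    for (k in adj[[j]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) ready <- sort(c(ready, k))
    }
  }
  if (length(order_) != length(names_)) {
    cyc <- setdiff(names_, order_)
    relmeta_stop("pipeline job graph contains a cycle among: %s",
                 paste(cyc, collapse = " -> "),
                 class = "relmeta_cycle_error")
  }
  order_
}

#' Parameters of one job
#'
#' Reads `<project_root>/<job_name>/job.star` and returns the job-option
#' variable/value pairs in file order. Values keep their text form (paths,
#' Yes/No booleans) untouched.
#'
#' @param project_root RELION project root directory.
#' @param job a job name (e.g. `"CtfFind/job003/"`) or a row of
#'   `graph$jobs`.
#' @return named character vector of parameters, in file order.
#' @export
job_parameters <- function(project_root, job) {
  name <- if (is.list(job) || is.data.frame(job)) job$name[1] else job
  path <- file.path(project_root, name, "job.star")
  if (!file.exists(path)) {
    relmeta_stop(
      "no job.star for job '%s' (looked at %s); pre-RELION-4 job layout?",
      name, path, class = "relmeta_lookup_error")
  }
  doc <- read_star(path)
  d <- pipeline_dialect
  tab <- get_table(doc, d$job_params)
  stats::setNames(as.character(tab[[d$job_val]]),
                  as.character(tab[[d$job_var]]))
}
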