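#' Fit the full neighbor-communication model to a dataset
#'
#' Runs the in-memory analysis end to end: per-cell-type HVG slices,
#' neighbor-type scores, per-type PLS2 fits with cross-validated component
#' selection, two-stage FDR coefficient filtering, per-type k-means gene
#' clustering and the aggregated, thresholded, path-attenuated cell-type
#' communication graph.
#'
#' @param dataset A `spatial_dataset`.
#' @param n_top HVGs per cell type (default 2000).
#' @param min_cells Minimum cells per type (default 10).
#' @param loess_span HVG mean-variance loess span (default 0.3).
#' @param kernel Neighbor-score kernel (default `"log10_ratio"`).
#' @param jitter,jitter_seed Coincident-cell jitter controls.
#' @param c_max Largest candidate component count; default
#'   `min(A, Z_a - 1, 10)` per type.
#' @param folds Cross-validation folds (default 10).
#' @param delta FDR threshold of both filter stages (default 0.05).
#' @param k_min,k_max k-means search range (defaults 2, 15).
#' @param cluster_restarts k-means restarts (default 10).
#' @param seed Seed for CV fold shuffles and k-means (default 0).
#' @return Object of class `communication_fit` with elements `slices`,
#'   `scores`, `fits`, `filtered`, `clusters`, `graph`, `ncomp`
#'   (selected components per type) and `params`.
#' @export
fit_communication <- function(dataset, n_top = 2000, min_cells = 10,
                              loess_span = 0.3, kernel = "log10_ratio",
                              jitter = FALSE, jitter_seed = 0,
                              c_max = NULL, folds = 10, delta = 0.05,
                              k_min = 2, k_max = 15, cluster_restarts = 10,
                              seed = 0) {
  validate_spatial_dataset(dataset)
  slices <- split_by_cell_type(dataset, n_top = n_top,
                               min_cells = min_cells,
                               loess_span = loess_span)
  scores <- neighbor_score_matrix(dataset, kernel = kernel,
                                  jitter = jitter, jitter_seed = jitter_seed)
  A <- length(scores$type_order)
  fits <- list(); filtered <- list(); clusters <- list(); ncomp <- c()
  for (a in names(slices)) {
    slice <- slices[[a]]
    x <- scores$zscored[slice$cell_index, , drop = FALSE]
    y <- slice$expression
    za <- nrow(y)
    cm <- if (is.null(c_max)) min(A, za - 1L, 10L) else min(c_max, A, za - 1L)
    sel <- select_components_cv(x, y, c_max = cm, folds = folds, seed = seed)
    fit <- fit_pls2(x, y, ncomp = sel$ncomp)
    fits[[a]] <- fit
    ncomp[a] <- sel$ncomp
    filtered[[a]] <- filter_coefficients(fit, x, y, delta = delta,
                                         cell_type = a)
    cl <- tryCatch(
      cluster_hvgs(filtered[[a]], k_min = k_min, k_max = k_max,
                   seed = seed, restarts = cluster_restarts),
      error = function(e) {
        warning("cell type '", a, "': clustering skipped (",
                conditionMessage(e), ")")
        NULL
      })
    if (!is.null(cl)) clusters[[a]] <- cl
  }
  graph <- NULL
  graphable <- intersect(names(filtered), names(clusters))
  if (length(graphable) >= 2) {
    graph <- communication_graph(filtered[graphable], clusters[graphable])
  } else {
    warning("fewer than 2 cell types with clustered genes; no graph built")
  }
  obj <- list(slices = slices, scores = scores, fits = fits,
              filtered = filtered, clusters = clusters, graph = graph,
              ncomp = ncomp,
              params = list(n_top = n_top, min_cells = min_cells,
                            loess_span = loess_span, kernel = kernel,
                            c_max = c_max, folds = folds, delta = delta,
                            k_min = k_min, k_max = k_max, seed = seed))
  class(obj) <- "communication_fit"
  obj
}

#' @export
print.communication_fit <- function(x, ...) {
  cat("communication_fit:", length(x$fits), "cell types\n")
  for (a in names(x$fits)) {
    nz <- sum(x$filtered[[a]]$coefficients != 0)
    cat("  ", a, ": ", x$ncomp[a], " component(s), ", nz,
        " retained coefficients",
        if (a %in% names(x$clusters))
          paste0(", k = ", x$clusters[[a]]$k), "\n", sep = "")
  }
  if (!is.null(x$graph)) print(x$graph)
  invisible(x)
}

#' @export
summary.communication_fit <- function(object, ...) {
  per_type <- data.frame(
    cell_type = names(object$fits),
    n_cells = vapply(object$slices[names(object$fits)],
                     function(s) length(s$cell_index), integer(1)),
    n_hvgs = vapply(object$slices[names(object$fits)],
                    function(s) length(s$hvg_ids), integer(1)),
    ncomp = unname(object$ncomp),
    retained = vapply(object$filtered,
                      function(f) sum(f$coefficients != 0), numeric(1)),
    k = vapply(names(object$fits), function(a)
      if (a %in% names(object$clusters)) object$clusters[[a]]$k
      else NA_integer_, integer(1)),
    row.names = NULL)
  out <- list(per_type = per_type,
              mean_weight = if (!is.null(object$graph))
                object$graph$mean_weight else NA,
              n_edges = if (!is.null(object$graph))
                sum(object$graph$thresholded != 0) else NA)
  class(out) <- "summary.communication_fit"
  out
}

#' @export
print.summary.communication_fit <- function(x, ...) {
  print(x$per_type)
  if (!is.na(x$n_edges)) {
    cat("graph:", x$n_edges, "edges above mean weight",
        format(x$mean_weight, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
coef.communication_fit <- function(object, ...) {
  lapply(object$filtered, function(f) f$coefficients)
}

#' @export
plot.communication_fit <- function(x, ...) {
  if (is.null(x$graph)) stop("no communication graph in this fit")
  plot(x$graph, ...)
}

default_config <- function() {
  list(
    input = list(expression = NULL, format = NULL, orientation = NULL,
                 coordinates = NULL, labels = NULL, annotations = NULL),
    hvg = list(n_top = 2000, loess_span = 0.3, min_cells_per_type = 10,
               overlap_mode = "ordered_fraction"),
    neighbor = list(kernel = "log10_ratio", jitter = FALSE, jitter_seed = 0),
    pls = list(c_max = NULL, folds = 10, seed = 0),
    filter = list(delta = 0.05),
    cluster = list(k_min = 2, k_max = 15, seed = 0, restarts = 10),
    graph = list(k_min_override = NULL),
    classify = list(folds = 10, seed = 0, hidden_units = 64,
                    strong_keywords = NULL, weak_keywords = NULL),
    out_dir = "spacomm_out")
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full pipeline from a config
#'
#' Stages, executed in order: load, hvg, scores, fit, filter, cluster,
#' graph, classify (the last is skipped when no annotation table is
#' configured). Every stage's outputs are written under `out_dir` and a
#' run manifest (config, seeds, package version, per-stage timings) is
#' emitted as JSON. Any stage error aborts with the stage name.
#'
#' @param config Path to a YAML config file, or an equivalent nested
#'   list. See `default_config` in the package source for keys; the
#'   `input` section must name `expression`, `coordinates` and `labels`
#'   files.
#' @param out_dir Overrides the config's output directory.
#' @return Invisibly, a list with the `communication_fit`, the label
#'   table / classifier report (if run) and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_names <- c("load", "hvg", "scores", "fit", "filter", "cluster",
                   "graph", "classify")
  manifest <- list(package_version = as.character(
                     utils::packageVersion("spacomm")),
                   r_version = R.version.string,
                   config = cfg, stages = list())
  t_stage <- function(name, status = "ok", secs = NA) {
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      name = name, status = status, seconds = round(secs, 3))
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (check the matching config section)", call. = FALSE)
    })
    t_stage(name, "ok", proc.time()[["elapsed"]] - t0)
    res
  }

  inp <- cfg$input
  dataset <- run_stage("load", {
    for (f in c(inp$expression, inp$coordinates, inp$labels)) {
      if (is.null(f) || !file.exists(f)) {
        stop("input file missing: ", if (is.null(f)) "(unset)" else f)
      }
    }
    expr <- load_expression(inp$expression, format = inp$format,
                            orientation = inp$orientation)
    assemble_dataset(expr, load_coordinates(inp$coordinates),
                     load_labels(inp$labels))
  })

  fit <- NULL
  slices <- run_stage("hvg", split_by_cell_type(
    dataset, n_top = cfg$hvg$n_top, min_cells = cfg$hvg$min_cells_per_type,
    loess_span = cfg$hvg$loess_span))
  scores <- run_stage("scores", neighbor_score_matrix(
    dataset, kernel = cfg$neighbor$kernel, jitter = cfg$neighbor$jitter,
    jitter_seed = cfg$neighbor$jitter_seed))
  # fit/filter/cluster/graph share fit_communication internals; staged here
  # so the manifest carries per-stage status and timing
  fits <- list(); filtered <- list(); clusters <- list(); ncomp <- c()
  A <- length(scores$type_order)
  run_stage("fit", {
    for (a in names(slices)) {
      x <- scores$zscored[slices[[a]]$cell_index, , drop = FALSE]
      y <- slices[[a]]$expression
      cm <- if (is.null(cfg$pls$c_max)) min(A, nrow(y) - 1L, 10L)
            else min(cfg$pls$c_max, A, nrow(y) - 1L)
      sel <- select_components_cv(x, y, c_max = cm, folds = cfg$pls$folds,
                                  seed = cfg$pls$seed)
      fits[[a]] <- fit_pls2(x, y, ncomp = sel$ncomp)
      ncomp[a] <- sel$ncomp
    }
  })
  run_stage("filter", {
    for (a in names(fits)) {
      x <- scores$zscored[slices[[a]]$cell_index, , drop = FALSE]
      filtered[[a]] <- filter_coefficients(
        fits[[a]], x, slices[[a]]$expression, delta = cfg$filter$delta,
        cell_type = a)
      write_outputs(filtered[[a]], cfg$out_dir)
    }
  })
  run_stage("cluster", {
    for (a in names(filtered)) {
      cl <- tryCatch(cluster_hvgs(
        filtered[[a]], k_min = cfg$cluster$k_min, k_max = cfg$cluster$k_max,
        seed = cfg$cluster$seed, restarts = cfg$cluster$restarts),
        error = function(e) {
          warning("cell type '", a, "': clustering skipped (",
                  conditionMessage(e), ")")
          NULL
        })
      if (!is.null(cl)) {
        clusters[[a]] <- cl
        write_outputs(cl, cfg$out_dir)
      }
    }
  })
  graph <- run_stage("graph", {
    graphable <- intersect(names(filtered), names(clusters))
    if (length(graphable) < 2) {
      warning("fewer than 2 cell types with clustered genes; no graph")
      NULL
    } else {
      g <- communication_graph(filtered[graphable], clusters[graphable],
                               k_min = cfg$graph$k_min_override)
      write_outputs(g, cfg$out_dir)
      g
    }
  })

  labels_tab <- NULL; report <- NULL
  if (!is.null(inp$annotations)) {
    run_stage("classify", {
      ann <- utils::read.table(inp$annotations, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "\"",
                               check.names = FALSE, comment.char = "")
      strong <- cfg$classify$strong_keywords
      weak <- cfg$classify$weak_keywords
      if (is.null(strong)) strong <- strong_keywords_default()
      if (is.null(weak)) weak <- weak_keywords_default()
      labels_tab <- label_genes_by_keywords(ann, strong, weak)
      write_outputs(as.data.frame(labels_tab), cfg$out_dir, "gene_labels")
      gene_set <- intersect(labels_tab$gene, dataset$gene_ids)
      feat <- build_gene_features(dataset, filtered, gene_set)
      lab <- labels_tab$label[match(gene_set, labels_tab$gene)]
      if (length(unique(lab)) < 2) {
        warning("gene labels are single-class; classifier skipped")
      } else {
        report <- train_eval_mlp(feat, lab, folds = cfg$classify$folds,
                                  seed = cfg$classify$seed,
                                  hidden_units = cfg$classify$hidden_units)
        write_outputs(report, cfg$out_dir)
      }
    })
  } else {
    t_stage("classify", "skipped (no annotations configured)", 0)
  }

  fit <- structure(list(slices = slices, scores = scores, fits = fits,
                        filtered = filtered, clusters = clusters,
                        graph = graph, ncomp = ncomp,
                        params = cfg[c("hvg", "neighbor", "pls", "filter",
                                       "cluster", "graph")]),
                   class = "communication_fit")
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = 8)
  invisible(list(fit = fit, labels = labels_tab, report = report,
                 manifest = manifest))
}
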