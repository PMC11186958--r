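# Population bundles: a directory holding graph_###.csv adjacency matrices,
# X.csv, node_attributes.csv, optionally truth.json, and manifest.json.

#' Write a population bundle to a directory
#'
#' @param data an [population_data()].
#' @param dir output directory (created if missing).
#' @param truth optional generative truth record (stored as truth.json).
#' @param extra optional named list merged into the manifest.
#' @return `dir`, invisibly.
#' @export
write_population_bundle <- function(data, dir, truth = NULL, extra = list()) {
  stopifnot(inherits(data, "ergmpop_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- data$n
  for (i in seq_len(n))
    write_adjacency(data$networks[[i]],
                    file.path(dir, sprintf("graph_%03d.csv", i)))
  write.csv(as.data.frame(data$X), file.path(dir, "X.csv"),
            row.names = FALSE)
  g1 <- data$networks[[1]]
  attrs <- data.frame(node = seq_len(g1$n_nodes),
                      hemisphere = g1$hemisphere %||% NA)
  if (!is.null(g1$homotopy_partner))
    attrs$homotopy_partner <- g1$homotopy_partner
  write.csv(attrs, file.path(dir, "node_attributes.csv"), row.names = FALSE)
  manifest <- c(list(
    n_networks = n, n_nodes = g1$n_nodes, terms = data$spec$terms,
    gwesp_decay = data$spec$gwesp_decay,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a population bundle
#'
#' @param dir bundle directory written by [write_population_bundle()].
#' @param spec an [ergm_spec()]; `NULL` reconstructs it from the manifest.
#' @return an [population_data()].
#' @export
read_population_bundle <- function(dir, spec = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(spec))
    spec <- ergm_spec(manifest$terms, gwesp_decay = manifest$gwesp_decay)
  attrs <- read.csv(file.path(dir, "node_attributes.csv"))
  hemi <- if (all(is.na(attrs$hemisphere))) NULL else
    as.character(attrs$hemisphere)
  partner <- if ("homotopy_partner" %in% names(attrs))
    as.integer(attrs$homotopy_partner) else NULL
  files <- sort(list.files(dir, pattern = "^graph_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) != manifest$n_networks)
    stop("bundle is missing graph files")
  networks <- lapply(files, read_adjacency, hemisphere = hemi,
                     homotopy_partner = partner)
  X <- as.matrix(read.csv(file.path(dir, "X.csv")))
  population_data(networks, X, spec)
}

#' Write posterior samples as tidy CSV plus a JSON run manifest
#'
#' The CSV has columns `chain`, `iteration`, `block` (beta / sigma_eps /
#' theta), `row`, `col`, `value`; the manifest records the configuration,
#' seed and acceptance diagnostics, enough to re-execute the run.
#'
#' @param fit an `ergmpop_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "ergmpop_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy_block <- function(arr, block) {
    d <- dim(arr)
    data.frame(chain = 1L,
               iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
               block = block,
               row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               col = rep(seq_len(d[3]), each = d[1] * d[2]),
               value = as.vector(arr))
  }
  tidy <- rbind(tidy_block(fit$beta, "beta"),
                tidy_block(fit$sigma_eps, "sigma_eps"),
                tidy_block(fit$theta, "theta"))
  write.csv(tidy, file.path(dir, "posterior.csv"), row.names = FALSE)
  manifest <- list(
    n_iter = fit$cfg$n_iter, burn_in = fit$cfg$burn_in,
    thin = fit$cfg$thin, parameterization = fit$cfg$parameterization,
    n_aux = fit$cfg$aux$n_aux, adapt_every = fit$cfg$adapt_every,
    adapt_until = fit$cfg$adapt_until, rng_seed = fit$cfg$rng_seed,
    n_kept = fit$n_kept, n_networks = fit$n, p = fit$p, q = fit$q,
    terms = fit$spec$terms, gwesp_decay = fit$spec$gwesp_decay,
    accept_theta = fit$accept_theta, accept_beta = fit$accept_beta,
    run_settings = paste(fit$cfg$n_iter, fit$cfg$burn_in,
                         fit$cfg$adapt_until, fit$cfg$aux$n_aux, sep = "/"),
    package_version = as.character(utils::packageVersion("ergmpop")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.csv(as.data.frame(fit$X), file.path(dir, "X.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read posterior samples written by [write_fit()]
#'
#' Reconstructs the draw arrays (not the full fit object).
#'
#' @param dir fit directory.
#' @return list with `beta`, `sigma_eps`, `theta` arrays, the `manifest`
#'   and design `X`.
#' @export
read_fit <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tidy <- read.csv(file.path(dir, "posterior.csv"))
  unblock <- function(block) {
    sub <- tidy[tidy$block == block, ]
    d <- c(max(sub$iteration), max(sub$row), max(sub$col))
    arr <- array(NA_real_, d)
    arr[cbind(sub$iteration, sub$row, sub$col)] <- sub$value
    arr
  }
  list(beta = unblock("beta"), sigma_eps = unblock("sigma_eps"),
       theta = unblock("theta"), manifest = manifest,
       X = as.matrix(read.csv(file.path(dir, "X.csv"))))
}
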