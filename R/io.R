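# Delimited-text interchange formats.  Individual-level data travel as a TSV
# with columns `iid, x, y, g1..gk` (plus optional covariate columns `c*`) and
# an optional JSON sidecar holding the simulation truth; collider summaries
# travel as a per-SNP TSV plus a YAML sidecar with the scalar fields.
# Doubles are written with 17 significant digits so round-trips are
# bit-exact.

#' Write individual-level data as TSV (+ JSON truth sidecar)
#'
#' @param data An `individual_data` object.
#' @param path Output TSV path.  When the data carry simulation truth, a
#'   sidecar `<path>.truth.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_individual_data <- function(data, path) {
  stopifnot(inherits(data, "individual_data"))
  df <- data.frame(iid = seq_along(data$exposure),
                   x = fmt_full(data$exposure),
                   y = fmt_full(data$outcome),
                   check.names = FALSE)
  G <- data$genotypes
  for (j in seq_len(ncol(G))) df[[colnames(G)[j]]] <- G[, j]
  if (!is.null(data$covariates)) {
    C <- data$covariates
    if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
    for (j in seq_len(ncol(C))) df[[colnames(C)[j]]] <- fmt_full(C[, j])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$truth)) {
    tr <- data$truth
    side <- list(
      config = unclass(tr$config),
      beta_xg = tr$effects$beta_xg, alpha = tr$effects$alpha,
      beta_yg = tr$beta_yg, beta_star = tr$beta_star, slope = tr$slope
    )
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(path)
}

#' Read individual-level data written by [write_individual_data()]
#'
#' @param path TSV path; a `<path>.truth.json` sidecar is picked up when
#'   present.
#' @return An `individual_data` object.
#' @export
read_individual_data <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  gcols <- grep("^g[0-9]+$", names(df), value = TRUE)
  ccols <- setdiff(names(df), c("iid", "x", "y", gcols))
  G <- as.matrix(df[gcols])
  storage.mode(G) <- "integer"
  covariates <- if (length(ccols)) as.matrix(df[ccols]) else NULL
  truth <- NULL
  side <- paste0(path, ".truth.json")
  if (file.exists(side)) {
    raw <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- raw$config
    cfg$seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)
    cfg <- structure(cfg, class = "sim_config")
    truth <- list(
      config = cfg,
      effects = structure(list(beta_xg = raw$beta_xg, alpha = raw$alpha),
                          class = "effect_vectors"),
      beta_yg = raw$beta_yg, beta_star = raw$beta_star, slope = raw$slope
    )
  }
  new_individual_data(G, df$x, df$y, covariates = covariates, truth = truth)
}

#' Write a collider summary as TSV (+ YAML sidecar)
#'
#' The per-SNP table has columns
#' `snp_id  beta_xg  se_xg  alpha_star  se_alpha_star`; the scalar fields
#' (`beta_star`, `se_beta_star`, `n`, `k`, regression family, covariates)
#' go to `<path>.yaml`.
#'
#' @param summary A `collider_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_collider_summary <- function(summary, path) {
  stopifnot(inherits(summary, "collider_summary"))
  df <- data.frame(snp_id = summary$snp_ids,
                   beta_xg = fmt_full(summary$beta_xg),
                   se_xg = fmt_full(summary$se_xg),
                   alpha_star = fmt_full(summary$alpha_star),
                   se_alpha_star = fmt_full(summary$se_alpha_star))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- summary$meta %||% list()
  yaml::write_yaml(list(
    beta_star = fmt_full(summary$beta_star),
    se_beta_star = fmt_full(summary$se_beta_star),
    n = summary$n, k = summary$k,
    family = meta$family %||% "gaussian",
    covariates = meta$covariates %||% character(0)
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a collider summary written by [write_collider_summary()]
#'
#' @param path TSV path (the `<path>.yaml` sidecar must exist).
#' @return A `collider_summary`.
#' @export
read_collider_summary <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", rep("numeric", 4)))
  meta <- yaml::read_yaml(side)
  new_collider_summary(
    snp_ids = df$snp_id,
    beta_xg = df$beta_xg, se_xg = df$se_xg,
    alpha_star = df$alpha_star, se_alpha_star = df$se_alpha_star,
    beta_star = as.numeric(meta$beta_star),
    se_beta_star = as.numeric(meta$se_beta_star),
    n = as.integer(meta$n), k = as.integer(meta$k),
    meta = list(family = meta$family,
                covariates = as.character(meta$covariates %||% character(0)))
  )
}
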