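# Data readers/writers and run manifests.

#' Read a delimited dataset for single-index regression
#'
#' Reads a CSV with header, selects one response and p covariate columns,
#' optionally applies the body-fat exclusion filter (drop rows whose percent
#' body fat is 0 or whose density is below 1), optionally standardizes each
#' covariate to mean 0 / SD 1, and optionally log-transforms the response.
#' Row order is preserved: train/test splits downstream are positional.
#'
#' @param path CSV file path.
#' @param response_col Name of the response column.
#' @param covariate_cols Character vector of covariate column names.
#' @param standardize Standardize covariates?
#' @param log_response Log-transform the response?
#' @param filter_percent_col,filter_density_col Optional column names
#'   enabling the named exclusion filter (rows with `percent == 0` or
#'   `density < 1` are dropped before any transformation).
#' @return List with `y`, `X` (matrix with named columns), `n`, `p` and the
#'   number of rows dropped by the filter.
#' @export
read_dataset <- function(path, response_col, covariate_cols,
                         standardize = FALSE, log_response = FALSE,
                         filter_percent_col = NULL,
                         filter_density_col = NULL) {
  df <- read.csv(path, header = TRUE)
  need <- c(response_col, covariate_cols, filter_percent_col,
            filter_density_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dropped <- 0L
  if (!is.null(filter_percent_col) || !is.null(filter_density_col)) {
    keep <- rep(TRUE, nrow(df))
    if (!is.null(filter_percent_col))
      keep <- keep & df[[filter_percent_col]] != 0
    if (!is.null(filter_density_col))
      keep <- keep & df[[filter_density_col]] >= 1
    dropped <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no rows left after filtering")
  X <- as.matrix(df[, covariate_cols, drop = FALSE])
  y <- df[[response_col]]
  if (!is.numeric(y) || !is.numeric(X))
    stop("response and covariates must be numeric")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (log_response) {
    if (any(y <= 0)) stop("log_response requires a positive response")
    y <- log(y)
  }
  if (standardize) X <- scale(X)[, , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("need more observations than covariates")
  list(y = as.numeric(y), X = X, n = nrow(X), p = ncol(X),
       dropped = dropped)
}

#' Write and re-read stored chain draws as delimited text
#'
#' One row per stored draw; columns are the index components, intercepts,
#' `sigma`, `gamma` and the link values. `read_chain()` restores the draw
#' matrices.
#'
#' @param fit A `bcqr_fit`.
#' @param path CSV path.
#' @return `write_chain()` the path invisibly; `read_chain()` a list of draw
#'   matrices.
#' @export
write_chain <- function(fit, path) {
  df <- data.frame(fit$beta,
                   setNames(as.data.frame(fit$alpha),
                            paste0("alpha", seq_len(ncol(fit$alpha)))),
                   sigma = fit$sigma, gamma = fit$gamma,
                   setNames(as.data.frame(fit$eta),
                            paste0("eta", seq_len(ncol(fit$eta)))),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  nm <- names(df)
  list(beta = as.matrix(df[, !grepl("^(alpha|eta)[0-9]+$|^sigma$|^gamma$", nm),
                           drop = FALSE]),
       alpha = as.matrix(df[, grepl("^alpha[0-9]+$", nm), drop = FALSE]),
       sigma = df$sigma, gamma = df$gamma,
       eta = as.matrix(df[, grepl("^eta[0-9]+$", nm), drop = FALSE]))
}

#' Plain-text manifest of a run
#'
#' Records the configuration, seed, package version and an input checksum so
#' a run can be reproduced bit-exactly.
#'
#' @param fit A `bcqr_fit`.
#' @param path Output path.
#' @param input_path Optional path of the input data file to checksum.
#' @return The path, invisibly.
#' @export
write_manifest <- function(fit, path, input_path = NULL) {
  ctl <- fit$control
  lines <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("bcqr"))),
    paste0("method: ", fit$method),
    paste0("n: ", nrow(fit$X)), paste0("p: ", ncol(fit$X)),
    paste0("M: ", fit$spec$M),
    paste0("n_iter: ", ctl$n_iter), paste0("n_burnin: ", ctl$n_burnin),
    paste0("thin: ", ctl$thin),
    paste0("seed: ", if (is.null(ctl$seed)) "NA" else ctl$seed),
    paste0("alpha_update: ", ctl$alpha_update),
    paste0("accept_beta: ", signif(fit$accept[["beta"]], 6)),
    paste0("accept_alpha: ", signif(fit$accept[["alpha"]], 6)),
    paste0("accept_gamma: ", signif(fit$accept[["gamma"]], 6)),
    paste0("scale_beta: ", signif(fit$scales[["beta"]], 6)),
    paste0("scale_alpha: ", signif(fit$scales[["alpha"]], 6)),
    paste0("scale_gamma: ", signif(fit$scales[["gamma"]], 6)))
  if (!is.null(input_path) && file.exists(input_path)) {
    lines <- c(lines,
               paste0("input_md5: ", unname(tools::md5sum(input_path))))
  }
  writeLines(lines, path)
  invisible(path)
}
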