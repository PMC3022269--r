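# Reading and writing pseudo-testcross datasets and results. Native formats
# are TSV for tables and JSON for structured results; genotype tokens accept
# both the "M1M3" and "1/3" dialects on input and are canonicalised
# (low allele index first) on output.

# parse one vector of genotype tokens into canonical gamete indices;
# returns NA where unparseable
.tq_parse_tokens <- function(tokens, prefix) {
  pat_named <- paste0("^", prefix, "([1-4])", prefix, "([1-4])$")
  pat_slash <- "^([1-4])/([1-4])$"
  a <- rep(NA_integer_, length(tokens))
  b <- rep(NA_integer_, length(tokens))
  named <- grepl(pat_named, tokens)
  a[named] <- as.integer(sub(pat_named, "\\1", tokens[named]))
  b[named] <- as.integer(sub(pat_named, "\\2", tokens[named]))
  slash <- !named & grepl(pat_slash, tokens)
  a[slash] <- as.integer(sub(pat_slash, "\\1", tokens[slash]))
  b[slash] <- as.integer(sub(pat_slash, "\\2", tokens[slash]))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(.tq_pairs[, 1L], .tq_pairs[, 2L])
  match(paste(lo, hi), key)
}

#' Read a pseudo-testcross dataset from TSV
#'
#' Reads a tab-separated file with header columns `id`, `marker`, optional
#' `qtl_true`, and `phenotype`. Genotype tokens may be written as `"M1M3"`
#' (or `"Q1Q3"` for `qtl_true`) or `"1/3"`, in either allele order; they are
#' canonicalised to low-index-first. Missing values are not permitted.
#'
#' @param path Path to the TSV file.
#' @return A `tetra_bc` data frame (see [simulate_dataset()]).
#' @export
read_backcross <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("id", "marker", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  midx <- .tq_parse_tokens(df$marker, "M")
  if (anyNA(midx)) {
    bad <- which(is.na(midx))[1L]
    stop(sprintf("unrecognised marker token '%s' at data line %d",
                 df$marker[bad], bad), call. = FALSE)
  }
  pheno <- suppressWarnings(as.numeric(df$phenotype))
  if (anyNA(pheno)) {
    bad <- which(is.na(pheno))[1L]
    stop(sprintf("non-numeric or missing phenotype at data line %d", bad),
         call. = FALSE)
  }
  out <- data.frame(id = df$id,
                    marker = gamete_labels("M")[midx],
                    phenotype = pheno,
                    stringsAsFactors = FALSE)
  if ("qtl_true" %in% names(df)) {
    qidx <- .tq_parse_tokens(df$qtl_true, "Q")
    if (anyNA(qidx)) {
      bad <- which(is.na(qidx))[1L]
      stop(sprintf("unrecognised QTL token '%s' at data line %d",
                   df$qtl_true[bad], bad), call. = FALSE)
    }
    out$qtl_true <- gamete_labels("Q")[qidx]
    out <- out[, c("id", "marker", "qtl_true", "phenotype")]
  }
  structure(out, class = c("tetra_bc", "data.frame"))
}

#' Write a pseudo-testcross dataset to TSV
#'
#' @param data A `tetra_bc` data frame.
#' @param path Output path.
#' @param keep_qtl Include the latent `qtl_true` column if present.
#' @return Invisibly, `path`.
#' @export
write_backcross <- function(data, path, keep_qtl = TRUE) {
  cols <- intersect(c("id", "marker",
                      if (keep_qtl) "qtl_true", "phenotype"), names(data))
  utils::write.table(as.data.frame(data)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tq_fit_as_list <- function(fit) {
  list(
    alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat, r_hat = fit$r_hat,
    sigma2_hat = fit$sigma2_hat,
    g_hat = as.list(fit$g_hat),
    means_hat = as.list(fit$means_hat),
    effects_hat = as.list(fit$effects_hat),
    loglik = fit$loglik, loglik_cond = fit$loglik_cond,
    n_iter = fit$n_iter, converged = fit$converged,
    start_used = fit$start_used, n_dropped = fit$n_dropped,
    constraint = fit$constraint
  )
}

#' Write fit, test or replication results
#'
#' Serialises a `tetra_fit`, `tetra_test` or `tetra_repstudy` object.
#' `format = "json"` writes a structured JSON document; `format = "tsv"`
#' writes a flat table — for replication studies, a three-row table (true
#' values, estimate means, standard errors in parentheses) mirroring the
#' customary Monte-Carlo summary layout with columns
#' `alpha, r, mu, a1..a3, d12..d34`.
#'
#' @param result The object to serialise.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param perm_path For `tetra_test` results with stored permutation
#'   statistics: optional path for a one-column TSV of the per-permutation
#'   statistics.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, format = c("json", "tsv"),
                          perm_path = NULL) {
  format <- match.arg(format)
  if (!is.null(perm_path) && inherits(result, "tetra_test") &&
      !is.null(result$perm_stats)) {
    utils::write.table(data.frame(statistic = result$perm_stats), perm_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (inherits(result, "tetra_fit")) {
    x <- .tq_fit_as_list(result)
    if (format == "json") {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    } else {
      flat <- c(alpha = x$alpha_hat, beta = x$beta_hat, r = x$r_hat,
                unlist(x$effects_hat), sigma2 = x$sigma2_hat,
                loglik = x$loglik)
      utils::write.table(data.frame(parameter = names(flat),
                                    estimate = unname(flat)),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else if (inherits(result, "tetra_test")) {
    x <- list(test = result$test, statistic = result$statistic,
              threshold = result$threshold, reject = result$reject,
              n_perm = result$n_perm, level = result$level,
              df = result$df, p_value = result$p_value)
    if (format == "json") {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    } else {
      utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else if (inherits(result, "tetra_repstudy")) {
    s <- summary(result)
    cols <- c("alpha", "r", .tq_effect_names)
    if (format == "json") {
      x <- list(truth = as.list(s["truth", cols]),
                mean = as.list(s["mean", cols]),
                sd = as.list(s["sd", cols]),
                n_converged = attr(s, "n_converged"),
                reps = attr(s, "reps"))
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    } else {
      tab <- rbind(
        truth = sprintf("%.3f", as.numeric(s["truth", cols])),
        mean = sprintf("%.3f", as.numeric(s["mean", cols])),
        se = sprintf("(%.3f)", as.numeric(s["sd", cols]))
      )
      colnames(tab) <- cols
      utils::write.table(cbind(row = rownames(tab), as.data.frame(tab)),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}

#' Read and write run configurations as key=value files
#'
#' A run configuration is a flat named list of scalar values (numbers,
#' logicals, strings) mirroring command-line flags, stored one `key=value`
#' per line. Values are parsed back as numeric or logical where possible,
#' so a configuration round-trips load-save-load identically.
#'
#' @param path File path.
#' @return `read_run_config()`: a named list. `write_run_config()`:
#'   invisibly, `path`.
#' @examples
#' cfg <- list(n = 400, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 1)
#' f <- tempfile()
#' write_run_config(cfg, f)
#' identical(read_run_config(f), cfg)
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  }
  vals <- lapply(kv, function(m) {
    v <- m[3L]
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 2L))
}

#' @rdname read_run_config
#' @param config Named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  vals <- vapply(config, function(v) {
    stopifnot(length(v) == 1L)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }, "")
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' Read a fit result written as JSON
#'
#' @param path Path to a JSON file written by [write_results()] for a
#'   `tetra_fit`.
#' @return A named list mirroring the serialised fields.
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
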