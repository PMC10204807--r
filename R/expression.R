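#' Read / write a gene-expression table
#'
#' The documented TSV interchange format: tab-separated with header
#' columns `gene`, `log2fc`, `detected` (true/false). Undetected genes
#' carry no log2 fold change (`NA`).
#'
#' @param path TSV file.
#' @return data.frame with columns `gene`, `log2fc`, `detected`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "detected")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop(sprintf("expression table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  tab$detected <- as.logical(tab$detected)
  tab$log2fc <- as.numeric(tab$log2fc)
  tab$log2fc[!tab$detected] <- NA_real_
  tab[, need]
}

#' @rdname read_expression_table
#' @param expression data.frame with the three columns above.
#' @export
write_expression_table <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Synthesize an expression table with a planted concordance level
#'
#' For every gene appearing in a GPR of a reaction with a directional flux
#' change, emits a log2 fold change whose sign matches the flux-change
#' sign with probability `agreement_p` (and is flipped otherwise);
#' magnitudes are drawn from a log-normal distribution
#' (`meanlog`/`sdlog`). Genes of reactions with `"unchanged"` flux get a
#' value inside the no-change band; genes of inactive reactions are
#' emitted as undetected. Deterministic for a fixed `seed`; the global RNG
#' state is restored on exit.
#'
#' @param model a [cbm_model()] with GPRs.
#' @param flux_fold_changes a [fold_change_table()].
#' @param agreement_p planted sign-agreement probability in `[0, 1]`.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal magnitude parameters (defaults give a
#'   median |log2FC| of 1).
#' @param unchanged_band half-width used for genes of unchanged reactions.
#' @return data.frame `gene`, `log2fc`, `detected`.
#' @export
synth_expression <- function(model, flux_fold_changes, agreement_p,
                             seed = 1L, meanlog = 0, sdlog = 0.5,
                             unchanged_band = 0.1) {
  if (agreement_p < 0 || agreement_p > 1)
    stop("agreement_p must lie in [0, 1]")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  out <- NULL
  for (i in seq_len(nrow(flux_fold_changes))) {
    rid <- flux_fold_changes$reaction[i]
    genes <- gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)])
    if (!length(genes)) next
    dir <- flux_fold_changes$direction[i]
    for (g in genes) {
      if (dir == "inactive-both") {
        out <- rbind(out, data.frame(gene = g, log2fc = NA_real_,
                                     detected = FALSE))
      } else if (dir == "unchanged") {
        out <- rbind(out, data.frame(
          gene = g,
          log2fc = stats::runif(1, -unchanged_band, unchanged_band),
          detected = TRUE))
      } else {
        sgn <- if (dir == "up") 1 else -1
        if (stats::runif(1) > agreement_p) sgn <- -sgn
        mag <- stats::rlnorm(1, meanlog = meanlog, sdlog = sdlog)
        out <- rbind(out, data.frame(gene = g,
                                     log2fc = sgn * (unchanged_band + mag),
                                     detected = TRUE))
      }
    }
  }
  ## a gene may serve several reactions; keep its first record
  out[!duplicated(out$gene), ]
}
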