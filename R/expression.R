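#' Call X-inactivation escapee genes
#'
#' An X-linked gene is flagged as an escapee when its female TPM is at
#' least `min_tpm` and the female/male ratio is at least `min_fold`.
#' A male TPM of zero is handled with a small pseudocount so the ratio
#' stays finite.
#'
#' @param expr Expression tibble with a `gene` column and one TPM column
#'   per group.
#' @param female_group,male_group Column names of the two groups.
#' @param x_genes Character vector of X-linked genes (subset of the table).
#' @param min_tpm Female TPM floor (default 1).
#' @param min_fold Female-over-male fold floor (default 1.5).
#' @param pseudocount Added to a zero male TPM before the ratio
#'   (default 0.01).
#' @return Tibble ranked by descending ratio with `female_tpm`, `male_tpm`,
#'   `ratio`, `flagged`.
#' @export
call_escapees <- function(expr, female_group, male_group, x_genes,
                          min_tpm = 1, min_fold = 1.5, pseudocount = 0.01) {
  for (g in c(female_group, male_group)) {
    if (!g %in% names(expr)) abort(sprintf("group column missing: %s", g))
  }
  if (!all(x_genes %in% expr$gene)) abort("x_genes not all present in the table")
  x <- filter(expr, .data$gene %in% x_genes)
  female <- x[[female_group]]
  male <- x[[male_group]]
  ratio <- female / ifelse(male == 0, pseudocount, male)
  tibble(gene = x$gene, female_tpm = female, male_tpm = male, ratio = ratio,
         flagged = female >= min_tpm & ratio >= min_fold) |>
    arrange(desc(.data$ratio))
}

#' Top-k escapees by female/male ratio
#'
#' @param calls Output of [call_escapees()].
#' @param k Number of genes (default 5).
#' @return The top `k` flagged rows.
#' @export
top_escapees <- function(calls, k = 5) {
  head(filter(calls, .data$flagged), k)
}

#' Select expression-matched control genes
#'
#' For each target gene, the `k` pool genes nearest in log TPM (with a
#' small pseudocount), sampled without replacement across targets in target
#' order; ties and contested nearest genes resolve deterministically (the
#' earlier target takes the nearer gene, the later one takes the next
#' nearest).
#'
#' @param targets Character vector of target genes.
#' @param pool Character vector of candidate controls (disjoint from
#'   `targets`).
#' @param expr Expression tibble with `gene` and the matching column.
#' @param k Controls per target (default 1).
#' @param tpm_col Column used for matching (default "female").
#' @return Tibble with `target`, `control`, `target_tpm`, `control_tpm`.
#' @export
match_controls <- function(targets, pool, expr, k = 1, tpm_col = "female") {
  pool <- setdiff(pool, targets)
  if (length(pool) < k * length(targets)) {
    abort("pool smaller than k * number of targets")
  }
  tpm <- setNames(expr[[tpm_col]], expr$gene)
  if (!all(c(targets, pool) %in% names(tpm))) abort("genes missing from table")
  lt <- function(g) log10(tpm[g] + 0.01)
  available <- pool
  out <- list()
  for (tg in targets) {
    d <- abs(lt(available) - lt(tg))
    sel <- available[order(d)][seq_len(k)]
    out[[tg]] <- tibble(target = tg, control = sel,
                        target_tpm = unname(tpm[tg]),
                        control_tpm = unname(tpm[sel]))
    available <- setdiff(available, sel)
  }
  list_rbind(out)
}
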