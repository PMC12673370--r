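#' @include AllClasses.R
NULL

#' Simulate a qPCR Ct table
#'
#' Generates a long-format Ct table with group-specific fold changes per
#' target gene. Target Ct values are
#' `baseline - log2(fold change) + noise`; the reference gene's Ct is
#' independent of group (`refCtMean + noise`). With `ctNoiseSd = 0` the
#' configured fold changes are recovered exactly by [deltaDeltaCt()].
#'
#' @param foldChanges named list: one named numeric per target gene giving
#'   the true fold change per group (control group must have fold 1).
#' @param nPerGroup samples per group (scalar or named numeric).
#' @param ctNoiseSd Gaussian Ct noise SD, default 0.
#' @param refGene reference gene name, default `"Actb"`.
#' @param refCtMean reference gene Ct level, default 20.
#' @param baselineCt target gene Ct at fold change 1, default 25
#'   (recycled over genes).
#' @param seed optional integer seed.
#' @return data.frame (`sample_id`, `group`, `gene`, `ct`).
#' @export
#' @examples
#' simulateQpcr(list(Mfn1 = c(Ctrl = 1, HPC = 2)), nPerGroup = 3)
simulateQpcr <- function(foldChanges, nPerGroup, ctNoiseSd = 0,
                         refGene = "Actb", refCtMean = 20,
                         baselineCt = 25, seed = NULL) {
  stopifnot(is.list(foldChanges), length(foldChanges) >= 1)
  if (any(unlist(foldChanges) <= 0)) stop("fold changes must be > 0")
  if (!is.null(seed)) set.seed(seed)
  groups <- names(foldChanges[[1]])
  if (is.null(groups)) stop("fold-change vectors must be named by group")
  if (length(nPerGroup) == 1L)
    nPerGroup <- setNames(rep(nPerGroup, length(groups)), groups)
  baselineCt <- rep_len(baselineCt, length(foldChanges))
  rows <- list()
  for (g in groups) {
    for (j in seq_len(nPerGroup[[g]])) {
      id <- sprintf("%s_%02d", g, j)
      ref <- refCtMean + if (ctNoiseSd > 0) stats::rnorm(1, 0, ctNoiseSd) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = id, group = g, gene = refGene, ct = ref)
      for (k in seq_along(foldChanges)) {
        fc <- foldChanges[[k]][[g]]
        ct <- baselineCt[k] - log2(fc) +
          if (ctNoiseSd > 0) stats::rnorm(1, 0, ctNoiseSd) else 0
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = id, group = g,
                     gene = names(foldChanges)[k], ct = ct)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the
#' control-group mean `dCt` of the same gene; the per-sample fold change is
#' `2^(-ddCt)`. Per-group fold changes are summarized as mean +/- SD.
#' Samples without a reference-gene Ct are dropped with a warning. Fold
#' changes are invariant under per-sample plate offsets (a constant added
#' to all Ct values of one sample cancels in `dCt`).
#'
#' @param ct data.frame (`sample_id`, `group`, `gene`, `ct`).
#' @param refGene reference gene name, default `"Actb"`.
#' @param controlGroup control group label, default `"Ctrl"`.
#' @return list with `perSample` (`sample_id`, `group`, `gene`, `d_ct`,
#'   `dd_ct`, `fold`) and `perGroup` (`gene`, `group`, `n`, `mean_fold`,
#'   `sd_fold`).
#' @export
deltaDeltaCt <- function(ct, refGene = "Actb", controlGroup = "Ctrl") {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  if (!any(ct$group == controlGroup)) stop("empty control group")
  ref <- ct[ct$gene == refGene, ]
  if (!nrow(ref)) stop(sprintf("reference gene %s absent", refGene))
  targets <- ct[ct$gene != refGene, ]
  refCt <- setNames(ref$ct, ref$sample_id)
  miss <- !(targets$sample_id %in% names(refCt))
  if (any(miss)) {
    warning("dropping sample(s) without reference Ct: ",
            paste(unique(targets$sample_id[miss]), collapse = ", "))
    targets <- targets[!miss, ]
  }
  targets$d_ct <- targets$ct - unname(refCt[targets$sample_id])
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(d) {
    ctrl <- d$d_ct[d$group == controlGroup]
    if (!length(ctrl)) stop(sprintf("empty control group for gene %s",
                                    d$gene[1]))
    d$dd_ct <- d$d_ct - mean(ctrl)
    d$fold <- 2^(-d$dd_ct)
    d
  }))
  rownames(out) <- NULL
  agg <- stats::aggregate(fold ~ gene + group, data = out, function(x)
    c(n = length(x), mean = mean(x), sd = stats::sd(x)))
  perGroup <- data.frame(gene = agg$gene, group = agg$group,
                         n = agg$fold[, "n"],
                         mean_fold = agg$fold[, "mean"],
                         sd_fold = agg$fold[, "sd"])
  list(perSample = out[, c("sample_id", "group", "gene", "d_ct", "dd_ct",
                           "fold")],
       perGroup = perGroup)
}

#' Reference-gene stability summary
#'
#' Per-group mean, SD and n of the reference gene's raw Ct values, the
#' summary used to verify that the housekeeping gene is unaffected by the
#' treatment.
#'
#' @param ct data.frame (`sample_id`, `group`, `gene`, `ct`).
#' @param refGene reference gene name, default `"Actb"`.
#' @return data.frame (`group`, `n`, `mean_ct`, `sd_ct`); `sd_ct` is `NA`
#'   for single-sample groups.
#' @export
referenceStability <- function(ct, refGene = "Actb") {
  ref <- ct[ct$gene == refGene, ]
  if (!nrow(ref)) stop(sprintf("reference gene %s absent", refGene))
  agg <- lapply(split(ref$ct, ref$group), function(x)
    data.frame(n = length(x), mean_ct = mean(x),
               sd_ct = if (length(x) > 1) stats::sd(x) else NA_real_))
  out <- do.call(rbind, agg)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
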