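#' Build a Ct table
#'
#' Long-format quantification-cycle table for relative expression: one row
#' per (sample, gene, biological replicate). The designated reference gene
#' must be measured for every sample/replicate; the calibrator group is the
#' baseline the 2^-ddCt fold changes are expressed against.
#'
#' @param data data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @param reference_gene endogenous control gene name.
#' @param calibrator calibrator group label.
#' @return data.frame of class `ct_table` with the design stored as
#'   attributes.
#' @export
ct_table <- function(data, reference_gene, calibrator) {
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("ct table lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(data$sample_id, data$gene, data$replicate)
  if (anyDuplicated(key))
    stop("duplicated (sample, gene, replicate) measurement: ",
         key[duplicated(key)][1])
  if (!reference_gene %in% data$gene)
    stop("reference gene ", reference_gene, " absent from the table")
  if (!calibrator %in% data$group)
    stop("calibrator group ", calibrator, " absent from the table")
  structure(as.data.frame(data), class = c("ct_table", "data.frame"),
            reference_gene = reference_gene, calibrator = calibrator)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample/replicate, dCt = Ct_target - Ct_reference; ddCt subtracts the
#' calibrator group's mean dCt for that gene; fold change is 2^-ddCt.
#' Group summaries average ddCt over biological replicates (the unit of
#' error) and report the fold change of the mean, `2^-mean(ddCt)`, with
#' the standard error on the ddCt (log2) scale; the calibrator group's own
#' summary fold change is therefore exactly 1.
#'
#' @param tab ct_table.
#' @return list with `per_replicate` (sample-level dCt, ddCt, fold change)
#'   and `summary` (per gene and group: `mean_ddct`, `se_ddct`, `fold_change`,
#'   `fc_lower`, `fc_upper` at +/- 1 SE, `n`).
#' @export
delta_delta_ct <- function(tab) {
  stopifnot(inherits(tab, "ct_table"))
  refg <- attr(tab, "reference_gene")
  cal <- attr(tab, "calibrator")
  ref <- tab[tab$gene == refg, c("sample_id", "replicate", "ct")]
  names(ref)[3] <- "ct_ref"
  tgt <- tab[tab$gene != refg, , drop = FALSE]
  m <- merge(tgt, ref, by = c("sample_id", "replicate"), all.x = TRUE)
  if (anyNA(m$ct_ref)) {
    bad <- unique(m$sample_id[is.na(m$ct_ref)])
    stop("missing reference-gene Ct for sample(s): ", paste(bad, collapse = ", "))
  }
  m$dct <- m$ct - m$ct_ref
  cal_mean <- aggregate(dct ~ gene, data = m[m$group == cal, , drop = FALSE],
                        FUN = mean)
  names(cal_mean)[2] <- "cal_dct"
  m <- merge(m, cal_mean, by = "gene", all.x = TRUE)
  if (anyNA(m$cal_dct)) stop("calibrator group lacks measurements for some gene")
  m$ddct <- m$dct - m$cal_dct
  m$fold_change <- 2^(-m$ddct)
  sumtab <- do.call(rbind, lapply(split(m, list(m$gene, m$group), drop = TRUE),
    function(d) {
      n <- nrow(d)
      se <- if (n >= 2) sd(d$ddct) / sqrt(n) else NA_real_
      data.frame(gene = d$gene[1], group = d$group[1], n = n,
                 mean_ddct = mean(d$ddct), se_ddct = se,
                 fold_change = 2^(-mean(d$ddct)),
                 fc_lower = 2^(-(mean(d$ddct) + ifelse(is.na(se), 0, se))),
                 fc_upper = 2^(-(mean(d$ddct) - ifelse(is.na(se), 0, se))),
                 stringsAsFactors = FALSE)
    }))
  rownames(sumtab) <- NULL
  m <- m[order(m$gene, m$group, m$sample_id, m$replicate),
         c("gene", "group", "sample_id", "replicate", "ct", "ct_ref",
           "dct", "ddct", "fold_change")]
  rownames(m) <- NULL
  list(per_replicate = m, summary = sumtab)
}

#' Compare expression between groups
#'
#' Per gene: group means with standard errors and the ratio of the
#' non-calibrator group's fold change to the calibrator's. No hypothesis
#' test is attached; the study reports means with standard errors only.
#'
#' @param ddct result of [delta_delta_ct()].
#' @param calibrator calibrator group label (defaults to the group whose
#'   summary fold change is 1).
#' @return data.frame per gene and non-calibrator group with columns
#'   `fold_change`, `se_ddct`, `ratio_vs_calibrator`, `se_flagged`.
#' @export
group_compare <- function(ddct, calibrator = NULL) {
  s <- ddct$summary
  if (!nrow(s))
    return(data.frame(gene = character(0), group = character(0),
                      fold_change = numeric(0), se_ddct = numeric(0),
                      ratio_vs_calibrator = numeric(0),
                      se_flagged = logical(0)))
  if (is.null(calibrator)) {
    cand <- s$group[abs(s$fold_change - 1) < 1e-12]
    calibrator <- unique(cand)[1]
  }
  cal <- s[s$group == calibrator, c("gene", "fold_change")]
  names(cal)[2] <- "cal_fc"
  oth <- s[s$group != calibrator, , drop = FALSE]
  out <- merge(oth, cal, by = "gene")
  out$ratio_vs_calibrator <- out$fold_change / out$cal_fc
  out$se_flagged <- is.na(out$se_ddct)
  if (any(out$se_flagged))
    warning("standard error unavailable for group(s) with a single replicate")
  out[, c("gene", "group", "fold_change", "se_ddct", "ratio_vs_calibrator",
          "se_flagged")]
}
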