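# Report assembly: a table of grouped morphometry statistics with
# significance marks, plus a stiffness block (per-group modulus, model
# force ratio, group comparison).

#' Assemble the analysis report
#'
#' Combines the grouped morphometry summary, the inner-vs-outer
#' comparisons, and the per-group modulus estimates into one report
#' object with a morphometry table (mean +/- SD, N, density,
#' significance marks) and a stiffness block (per-group mean +/- SD
#' modulus, model force ratio, Welch p).
#'
#' @param morphometry A [summarize_groups()] result.
#' @param comparisons Named list of `group_comparison` objects; names
#'   like `"day20_cell"`, `"day20_nucleus"`, `"day20_density"` attach
#'   marks to the matching age's rows.
#' @param moduli Named list, one element per age, each with `mean_pa`,
#'   `sd_pa`, `n`.
#' @param strict If `TRUE`, a missing group is an error; otherwise the
#'   row renders with an `NA` gap marker.
#' @return Object of class `spheromech_report` with elements `table`
#'   (data frame), `stiffness` (data frame), `force_ratio` and
#'   `stiffness_p`.
#' @export
build_report <- function(morphometry, comparisons = list(), moduli = list(),
                         strict = FALSE) {
  stopifnot(inherits(morphometry, "morphometry_summary"))
  a <- morphometry$areas
  d <- morphometry$density
  ages <- unique(a$age)
  rows <- list()
  for (age in ages) for (rg in c("inner", "outer")) {
    ai <- a[a$age == age & a$region == rg, ]
    di <- d[d$age == age & d$region == rg, ]
    if (nrow(ai) == 0L || nrow(di) == 0L) {
      abort_if(strict, sprintf("missing group: %s/%s", age, rg))
      rows[[paste(age, rg)]] <- data.frame(
        age = age, region = rg, cell_mean = NA_real_, cell_sd = NA_real_,
        cell_n = NA_integer_, nucleus_mean = NA_real_, nucleus_sd = NA_real_,
        density_mean = NA_real_, density_sd = NA_real_,
        cell_mark = "", nucleus_mark = "", density_mark = "")
      next
    }
    mk <- function(kind) {
      cmp <- comparisons[[paste0(age, "_", kind)]]
      if (is.null(cmp)) "" else cmp$mark
    }
    rows[[paste(age, rg)]] <- data.frame(
      age = age, region = rg,
      cell_mean = ai$cell_mean, cell_sd = ai$cell_sd, cell_n = ai$cell_n,
      nucleus_mean = ai$nucleus_mean, nucleus_sd = ai$nucleus_sd,
      density_mean = di$mean, density_sd = di$sd,
      cell_mark = mk("cell"), nucleus_mark = mk("nucleus"),
      density_mark = mk("density"))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  stiffness <- NULL; ratio <- NA_real_; p_stiff <- NA_real_
  if (length(moduli)) {
    stiffness <- do.call(rbind, lapply(names(moduli), function(g)
      data.frame(group = g, mean_pa = moduli[[g]]$mean_pa,
                 sd_pa = moduli[[g]]$sd_pa, n = moduli[[g]]$n)))
    if (nrow(stiffness) == 2L) {
      hi <- which.max(stiffness$mean_pa); lo <- setdiff(1:2, hi)
      ratio <- force_ratio(stiffness$mean_pa[hi], stiffness$mean_pa[lo])
      if (all(stiffness$n >= 2L))
        p_stiff <- welch_from_summary(
          stiffness$mean_pa[1], stiffness$sd_pa[1], stiffness$n[1],
          stiffness$mean_pa[2], stiffness$sd_pa[2], stiffness$n[2])$p
    }
  }
  structure(list(table = table, stiffness = stiffness,
                 force_ratio = ratio, stiffness_p = p_stiff),
            class = "spheromech_report")
}

#' Write / read the report morphometry table as CSV
#'
#' The CSV mirrors the report table one row per age x region; reading it
#' back reproduces the in-memory table exactly.
#'
#' @param report A [build_report()] object.
#' @param path CSV path.
#' @return `write_report_csv` returns `path` invisibly;
#'   `read_report_csv` returns the table data frame.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("cell_mark", "nucleus_mark", "density_mark"))
    tab[[cl]] <- ifelse(is.na(tab[[cl]]), "", tab[[cl]])
  tab
}

#' Render the report as Markdown
#'
#' @param report A [build_report()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_md <- function(report, path) {
  t <- report$table
  lines <- c("# Spheroid analysis report", "",
             "## Morphometry (complete cells, pooled)", "",
             "| age | region | cell (um^2) | nucleus (um^2) | space density (%) |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(t))) {
    fmt <- function(m, s, mk, dg = 0)
      if (is.na(m)) "missing" else
        sprintf("%.*f +/- %.*f%s", dg, m, dg, s, mk)
    lines <- c(lines, sprintf(
      "| %s | %s | %s (N = %s) | %s | %s |",
      t$age[i], t$region[i],
      fmt(t$cell_mean[i], t$cell_sd[i], t$cell_mark[i]), t$cell_n[i],
      fmt(t$nucleus_mean[i], t$nucleus_sd[i], t$nucleus_mark[i]),
      fmt(t$density_mean[i], t$density_sd[i], t$density_mark[i], 1)))
  }
  if (!is.null(report$stiffness)) {
    lines <- c(lines, "", "## Stiffness", "",
               "| group | E (Pa) | n |", "|---|---|---|",
               sprintf("| %s | %.0f +/- %.0f | %d |",
                       report$stiffness$group, report$stiffness$mean_pa,
                       report$stiffness$sd_pa, report$stiffness$n),
               "",
               sprintf("Model force ratio (stiff/soft): %.2f; Welch p = %.2g",
                       report$force_ratio, report$stiffness_p))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.spheromech_report <- function(x, ...) {
  print(x$table)
  if (!is.null(x$stiffness)) {
    print(x$stiffness)
    cat(sprintf("force ratio %.2f, stiffness p = %.3g\n",
                x$force_ratio, x$stiffness_p))
  }
  invisible(x)
}
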