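# Shared fixtures: the Harare reference-period roster counts used across
# the planning tests.

harare_counts <- function() {
  period_counts(
    label = c("1 month", "3 months", "6 months", "12 months", "24 months"),
    months = c(1, 3, 6, 12, 24),
    m = c(85, 560, 952, 1542, 2227)
  )
}

harare_csv <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
  }
  path <- file.path(dir, "periods.csv")
  writeLines(c("label,months,count",
               "1 month,1,85",
               "3 months,3,560",
               "6 months,6,952",
               "12 months,12,1542",
               "24 months,24,2227"), path)
  path
}
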