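setMethod("show", "MRIVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRIVolume %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  v <- object@data
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume %d x %d x %d\n", d[1], d[2], d[3]))
  tb <- table(object@labels)
  cat("  labels:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
})

setMethod("show", "GibbsFilterPair", function(object) {
  d <- dim(object@gx)
  cat(sprintf("GibbsFilterPair on a %d x %d centered frequency grid\n",
              d[1], d[2]))
  cat(sprintf("  Gx in [%.3f, %.3f]; Gx + Gy = 1 exactly\n",
              min(object@gx), max(object@gx)))
})

setMethod("show", "BiasFieldResult", function(object) {
  f <- volData(object@field)[object@mask]
  cat(sprintf("BiasFieldResult: %d iteration(s), %s\n", object@iterations,
              if (object@converged) "converged" else "iteration cap reached"))
  cat(sprintf("  field over mask: range [%.4f, %.4f], CV %.4f\n",
              min(f), max(f), sd(f) / mean(f)))
})

setMethod("show", "NyulModel", function(object) {
  cat(sprintf("NyulModel: %d landmarks on standard scale [%g, %g]\n",
              length(object@landmarks), object@standardRange[1],
              object@standardRange[2]))
  cat("  percentiles:", paste(object@schedule, collapse = ", "), "\n")
  cat("  landmarks:", paste(signif(object@landmarks, 4), collapse = ", "),
      "\n")
})

setMethod("show", "PreprocSequence", function(object) {
  kinds <- vapply(object@stages, function(s) s@kind, "")
  cat(sprintf("PreprocSequence '%s': %s\n", object@name,
              if (length(kinds)) paste(kinds, collapse = " -> ") else
                "(empty)"))
})

setMethod("show", "RunRecord", function(object) {
  cat(sprintf("RunRecord for '%s' (mriprep %s)\n", object@sequenceName,
              object@version))
  if (nrow(object@stats)) {
    df <- object@stats
    df[-1] <- lapply(df[-1], signif, digits = 4)
    print(df, row.names = FALSE)
  } else cat("  (no stages)\n")
})
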