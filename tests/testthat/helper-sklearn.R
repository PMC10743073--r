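# Cross-check helper: run scikit-learn's LocalOutlierFactor (via the python
# on PATH) on a feature matrix for several k and return the LOF scores.
# Used only on tie-free datasets, where the tie-inclusive neighbourhood
# convention coincides with sklearn's fixed-k one.

sklearn_lof <- function(X, ks) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.neighbors import LocalOutlierFactor",
    "X = np.loadtxt(sys.argv[1], delimiter=',')",
    "ks = [int(k) for k in sys.argv[3].split(',')]",
    "out = []",
    "for k in ks:",
    "    m = LocalOutlierFactor(n_neighbors=k, algorithm='brute')",
    "    m.fit(X)",
    "    out.append(-m.negative_outlier_factor_)",
    "np.savetxt(sys.argv[2], np.column_stack(out), fmt='%.17g', delimiter=',')"
  ), script)
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  utils::write.table(format(X, digits = 17, scientific = TRUE), fin,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  status <- system2("python", c(script, fin, fout, paste(ks, collapse = ",")),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("python/scikit-learn cross-check failed to run")
  out <- as.matrix(utils::read.table(fout, sep = ","))
  dimnames(out) <- list(NULL, paste0("k", ks))
  out
}
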