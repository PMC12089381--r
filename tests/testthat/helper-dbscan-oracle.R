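# Reference DBSCAN oracle: scikit-learn run on precomputed minimum-image
# distance matrices, batched through a single python call.  sklearn's
# min_samples counts the point itself, so core(n_min neighbours) maps to
# min_samples = n_min + 1.

sklearn_dbscan_batch <- function(configs) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(configs, function(cf)
    list(pos = unname(as.matrix(cf$positions)), box = cf$box, eps = cf$eps,
         n_min = cf$n_min))
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from sklearn.cluster import DBSCAN",
    sprintf("cfgs = json.load(open('%s'))", infile),
    "out = []",
    "for cf in cfgs:",
    "    X = np.asarray(cf['pos'], dtype=float); box = cf['box']",
    "    d = X[:, None, :] - X[None, :, :]",
    "    d -= box * np.round(d / box)",
    "    D = np.sqrt((d ** 2).sum(-1))",
    "    lab = DBSCAN(eps=cf['eps'], min_samples=cf['n_min'] + 1,",
    "                 metric='precomputed').fit(D).labels_",
    "    out.append([int(v) for v in lab])",
    sprintf("json.dump(out, open('%s', 'w'))", outfile)), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)      # oracle unavailable
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

# TRUE when two labelings define the same partition with identical noise
same_partition <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  noise_a <- a <= 0; noise_b <- b < 0   # package: 0, sklearn: -1
  if (!identical(noise_a, noise_b)) return(FALSE)
  ka <- a[!noise_a]; kb <- b[!noise_b]
  if (length(ka) == 0) return(TRUE)
  identical(as.integer(factor(ka, levels = unique(ka))),
            as.integer(factor(kb, levels = unique(kb))))
}
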