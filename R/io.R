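#' Write / read a key = value configuration file
#'
#' Plain structured text: one `key = value` per line, `#` comments allowed,
#' logical values as true/false.  Units are documented in the written
#' header.
#'
#' @param config `phos_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  hdr <- c("# phosdyn run configuration",
           "# units: dt ps; temperature K; friction, rot_friction ps^-1;",
           "#        box_side, contact_cutoff, reservoir_distance nm;",
           "#        dmu_p kJ/mol; strides in MD steps")
  keys <- setdiff(names(config), character())
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    v <- if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
    paste(k, "=", v)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_config
#' @param path file to read.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (v %in% c("true", "false")) return(v == "true")
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write / read an event log as TSV
#'
#' @param events event data frame from a `phos_trajectory`.
#' @param path file path.
#' @return `path` / the data frame.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(time = "numeric", kind = "character",
                                   site = "integer", dU = "numeric",
                                   prob = "numeric", accepted = "logical"))
}

#' Write / read trajectory frames as TSV
#'
#' Long-format plain-text container: one row per frame with time (ns),
#' total potential energy, per-site chemical state and per-site
#' contact-criterion distance columns.  Exact round-trip of the numeric
#' values is guaranteed through full-precision formatting.
#'
#' @param traj `phos_trajectory`.
#' @param path file path.
#' @return `path` / list of frame vectors.
#' @export
write_trajectory_tsv <- function(traj, path) {
  fr <- traj$frames
  nsite <- ncol(fr$chem)
  df <- data.frame(time = fr$time, energy = fr$energy)
  for (s in seq_len(nsite)) df[[paste0("chem", s)]] <- fr$chem[, s]
  for (s in seq_len(nsite)) df[[paste0("dist", s)]] <- fr$site_dist[, s]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  fmt <- do.call(paste, c(lapply(df, function(col)
    if (is.integer(col)) as.character(col)
    else sprintf("%.17g", col)), sep = "\t"))
  writeLines(fmt, con)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.delim(path)
  chem_cols <- grep("^chem", names(df))
  dist_cols <- grep("^dist", names(df))
  list(time = df$time, energy = df$energy,
       chem = as.matrix(df[chem_cols]),
       site_dist = as.matrix(df[dist_cols]))
}

#' Run manifest
#'
#' Records the configuration snapshot, seed, package version and input
#' checksums so every output is traceable; byte-identical runs produce
#' identical manifests.
#'
#' @param config `phos_config`.
#' @param inputs named character vector of input file paths (checksummed).
#' @param outputs character vector of produced files.
#' @return manifest list.
#' @export
run_manifest <- function(config, inputs = character(), outputs = character()) {
  sums <- vapply(inputs, function(f)
    as.character(tools::md5sum(f)), character(1))
  list(package = "phosdyn",
       version = as.character(utils::packageVersion("phosdyn")),
       seed = config$seed,
       config = unclass(config),
       input_md5 = as.list(sums),
       outputs = outputs)
}

#' @rdname run_manifest
#' @param manifest manifest list.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
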