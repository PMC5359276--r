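# All writes go through a temp-file + rename contract so an aborted
# session never leaves a truncated file behind.
write_atomic <- function(write_fun, path) {
  # the temp name keeps the real extension so format-sniffing writers
  # (NIfTI .nii/.nii.gz) behave identically on the temp file
  tmp <- file.path(dirname(path),
                   paste0(".tmp", Sys.getpid(), "-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path,
                                    call. = FALSE)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(function(p)
    utils::write.table(df, p, sep = "\t", row.names = FALSE,
                       quote = FALSE), path)
}

#' Write an EEG stream as a BrainVision triplet
#'
#' Emits the interoperable subset of the format: an INI-style `.vhdr`
#' header, a `.vmrk` marker file and IEEE float32 multiplexed binary
#' `.eeg` data. Marker positions are converted to the file's 1-based
#' convention (they already are 1-based in the stream, so they pass
#' through). All three files are written atomically.
#'
#' @param stream an [eeg_stream()] with at least one channel.
#' @param path base path or the `.vhdr` path; the triplet shares the
#'   stem.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(stream, path) {
  if (nrow(stream$data) == 0L)
    stop("refusing to write a stream with no channels", call. = FALSE)
  stem <- sub("\\.vhdr$", "", path)
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(stream$data)),
    paste0("SamplingInterval=", format(1e6 / stream$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(stream$data)),
            stream$channel_labels))
  write_atomic(function(p) writeLines(hdr, p, useBytes = TRUE), vhdr)

  mk <- stream$markers
  lines <- c("Brain Vision Data Exchange Marker File, Version 1.0",
             "",
             "[Common Infos]",
             "Codepage=UTF-8",
             paste0("DataFile=", base, ".eeg"),
             "",
             "[Marker Infos]")
  if (nrow(mk))
    lines <- c(lines, sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(mk)),
                              mk$kind, mk$label, mk$sample))
  write_atomic(function(p) writeLines(lines, p, useBytes = TRUE), vmrk)

  # multiplexed float32: all channels of sample 1, then sample 2, ...
  write_atomic(function(p) {
    con <- file(p, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(stream$data), con, size = 4L, endian = "little")
  }, eeg)
  invisible(vhdr)
}

parse_ini <- function(lines) {
  out <- list()
  section <- ""
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      if (section == "") next
      stop("malformed header line ", i, ": '", lines[i], "'", call. = FALSE)
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    out[[section]][[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  out
}

#' Read a BrainVision triplet into an EEG stream
#'
#' Reads the binary multiplexed IEEE float32 dialect written by
#' [write_brainvision()] (16-bit integer data are tolerated on read).
#' A missing marker file yields an empty marker table with a warning.
#'
#' @param path the `.vhdr` path.
#' @return an [eeg_stream()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop("no such header: ", path, call. = FALSE)
  ini <- parse_ini(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("header without [Common Infos]", call. = FALSE)
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  if (!identical(ci$DataOrientation, "MULTIPLEXED"))
    stop("unsupported DataOrientation: ", ci$DataOrientation, call. = FALSE)
  fmt <- ini[["Binary Infos"]]$BinaryFormat
  labels <- vapply(seq_len(nch), function(i) {
    entry <- ini[["Channel Infos"]][[paste0("Ch", i)]]
    if (is.null(entry)) stop("missing Channel Infos entry Ch", i,
                             call. = FALSE)
    strsplit(entry, ",", fixed = TRUE)[[1]][1]
  }, character(1))

  dir <- dirname(path)
  efile <- file.path(dir, ci$DataFile)
  sz <- file.size(efile)
  con <- file(efile, "rb")
  on.exit(close(con), add = TRUE)
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw <- readBin(con, numeric(), n = sz %/% 4L, size = 4L,
                   endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw <- readBin(con, integer(), n = sz %/% 2L, size = 2L,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  data <- matrix(raw, nrow = nch)

  markers <- data.frame(kind = character(), sample = integer(),
                        label = character())
  mfile <- file.path(dir, ci$MarkerFile %||% "")
  if (!is.null(ci$MarkerFile) && file.exists(mfile)) {
    mini <- parse_ini(readLines(mfile, warn = FALSE))
    mi <- mini[["Marker Infos"]]
    if (!is.null(mi)) {
      rows <- lapply(mi, function(entry) {
        f <- strsplit(entry, ",", fixed = TRUE)[[1]]
        data.frame(kind = f[1], sample = as.integer(f[3]),
                   label = if (length(f) >= 2) f[2] else "")
      })
      markers <- do.call(rbind, rows)
      markers <- markers[markers$kind != "New Segment", , drop = FALSE]
      rownames(markers) <- NULL
    }
  } else {
    warning("no marker file found: stream has empty markers")
  }
  eeg_stream(data, fs, labels, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume series as 4D NIfTI-1
#'
#' Voxel data, the affine and the TR (stored in pixdim\[4\]) round-trip
#' exactly.
#'
#' @param series a [volume_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  vox <- abs(diag(series$affine)[1:3])
  RNifti::pixdim(img) <- c(vox, series$tr)
  write_atomic(function(p) RNifti::writeNifti(img, p), path)
  invisible(path)
}

#' Read a 4D NIfTI-1 file into a volume series
#'
#' @param path a `.nii` / `.nii.gz` file with 3D or 4D payload (3D is
#'   promoted to a single-volume series; lower dimensionality is an
#'   error).
#' @return a [volume_series()]; TR from pixdim\[4\].
#' @export
read_nifti_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("need a 3D or 4D NIfTI image, got ", length(dim(arr)), "D",
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4) pd[4] else 1
  if (!is.finite(tr) || tr <= 0) tr <- 1
  affine <- diag(c(pd[1:3], 1))
  volume_series(arr, tr = tr, affine = affine)
}

#' Write a 3D mask or map as NIfTI-1
#'
#' @param x a [roi_mask()] (written as 0/1) or a 3D array (z map).
#' @param path output path.
#' @param grid_shape required when `x` is a bare index vector.
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(x, path, grid_shape = NULL) {
  arr <- if (inherits(x, "roi_mask")) {
    a <- array(0, x$grid_shape)
    a[x$voxels] <- 1
    a
  } else if (is.array(x) && length(dim(x)) == 3L) {
    x
  } else stop("x must be a roi_mask or 3D array", call. = FALSE)
  write_atomic(function(p) RNifti::writeNifti(RNifti::asNifti(arr), p),
               path)
  invisible(path)
}

#' Load and validate a YAML configuration
#'
#' Schema-checked loader for simulation and protocol configurations:
#' unknown keys are rejected (all of them named at once), defaults are
#' filled by the respective constructors, and the returned object
#' carries the file's MD5 as `source_hash` for provenance.
#'
#' @param path YAML file with a top-level `kind: simulation` or
#'   `kind: protocol` plus the constructor's fields.
#' @return a validated [sim_config()] or [protocol_spec()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  kind <- y$kind %||% stop("config needs a 'kind' key", call. = FALSE)
  y$kind <- NULL
  ctor <- switch(kind,
                 simulation = sim_config,
                 protocol = protocol_spec,
                 stop("unknown config kind: ", kind, call. = FALSE))
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (kind == "simulation" && !is.null(y$grid_shape))
    y$grid_shape <- as.integer(unlist(y$grid_shape))
  if (kind == "simulation" && !is.null(y$active_block))
    y$active_block <- lapply(y$active_block, function(v) as.integer(unlist(v)))
  if (kind == "protocol" && !is.null(y$task_s))
    y$task_s <- as.numeric(unlist(y$task_s))
  obj <- do.call(ctor, y)
  attr(obj, "source_hash") <- unname(tools::md5sum(path))
  obj
}

#' Write the tidy feedback log
#'
#' One row per update tick and modality: `time_s`, `block`, `modality`,
#' `raw`, `baseline`, `normalized`, `combined`. Written atomically as
#' CSV.
#'
#' @param nfb_log data frame in that shape (as produced by
#'   [run_session()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_nfb_log <- function(nfb_log, path) {
  write_atomic(function(p) utils::write.csv(nfb_log, p, row.names = FALSE),
               path)
  invisible(path)
}
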