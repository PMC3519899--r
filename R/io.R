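# Volume file I/O (NRRD, NIfTI), case manifests and the batch study driver.
#
# NRRD is the primary on-disk format (the native format of the Slicer
# ecosystem); a minimal NRRD0004 reader/writer is implemented here because no
# NRRD package is available on CRAN/Bioconductor in this stack. NIfTI-1 goes
# through RNifti. Direction/orientation header fields are carried through
# untouched but ignored by computation (everything here is grid-local).

nrrd_type_table <- list(
  "signed char" = list(size = 1L, what = "integer", signed = TRUE),
  "int8" = list(size = 1L, what = "integer", signed = TRUE),
  "int8_t" = list(size = 1L, what = "integer", signed = TRUE),
  "uchar" = list(size = 1L, what = "integer", signed = FALSE),
  "unsigned char" = list(size = 1L, what = "integer", signed = FALSE),
  "uint8" = list(size = 1L, what = "integer", signed = FALSE),
  "uint8_t" = list(size = 1L, what = "integer", signed = FALSE),
  "short" = list(size = 2L, what = "integer", signed = TRUE),
  "short int" = list(size = 2L, what = "integer", signed = TRUE),
  "signed short" = list(size = 2L, what = "integer", signed = TRUE),
  "int16" = list(size = 2L, what = "integer", signed = TRUE),
  "int16_t" = list(size = 2L, what = "integer", signed = TRUE),
  "ushort" = list(size = 2L, what = "integer", signed = FALSE),
  "unsigned short" = list(size = 2L, what = "integer", signed = FALSE),
  "uint16" = list(size = 2L, what = "integer", signed = FALSE),
  "int" = list(size = 4L, what = "integer", signed = TRUE),
  "signed int" = list(size = 4L, what = "integer", signed = TRUE),
  "int32" = list(size = 4L, what = "integer", signed = TRUE),
  "int32_t" = list(size = 4L, what = "integer", signed = TRUE),
  "float" = list(size = 4L, what = "double", signed = TRUE),
  "double" = list(size = 8L, what = "double", signed = TRUE)
)

parse_nrrd_vectors <- function(value) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries -> NULL
  toks <- regmatches(value, gregexpr("\\(([^)]*)\\)|none", value))[[1L]]
  lapply(toks, function(t) {
    if (t == "none") return(NULL)
    as.numeric(strsplit(gsub("[()]", "", t), "[, ]+")[[1L]])
  })
}

#' Read an NRRD volume
#'
#' Minimal NRRD0004 reader: 3D volumes, `raw`, `gzip` or `ascii` encodings,
#' the common scalar types, and spacing taken from `spacings` or from the row
#' norms of axis-aligned `space directions`. Unsupported or missing header
#' fields raise errors naming the offending field.
#'
#' @param path Path to a `.nrrd` file.
#' @param kind `"auto"` (integer-typed files become label maps), `"image"` or
#'   `"labelmap"`.
#' @return A [scalar_volume()] or [label_map()].
#' @export
read_nrrd <- function(path, kind = c("auto", "image", "labelmap")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(0x0a))
  hdr_end <- NA_integer_
  for (p in nl) {
    if (p < length(bytes) && bytes[p + 1L] == as.raw(0x0a)) {
      hdr_end <- p + 1L
      break
    }
    if (p + 2L <= length(bytes) && bytes[p + 1L] == as.raw(0x0d) &&
        bytes[p + 2L] == as.raw(0x0a)) {
      hdr_end <- p + 2L
      break
    }
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line ending the header")
  lines <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1L)]), "\r?\n")[[1L]]
  if (!grepl("^NRRD000[0-9]$", lines[1L])) {
    stop("not an NRRD file (bad magic): ", path)
  }
  lines <- lines[-1L]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) kv[[tolower(trimws(m[2L]))]] <- trimws(m[3L])
  }
  need <- function(field) {
    if (is.null(kv[[field]])) stop("NRRD header is missing field: ", field)
    kv[[field]]
  }
  if (as.integer(need("dimension")) != 3L) {
    stop("only 3D NRRD volumes are supported (dimension: ", kv$dimension, ")")
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1L]])
  if (length(sizes) != 3L || any(sizes < 1L)) {
    stop("invalid NRRD header field sizes: ", kv$sizes)
  }
  type <- tolower(need("type"))
  tp <- nrrd_type_table[[type]]
  if (is.null(tp)) stop("unsupported NRRD type: ", type)
  spacing <- NULL
  directions <- NULL
  if (!is.null(kv[["space directions"]])) {
    directions <- parse_nrrd_vectors(kv[["space directions"]])
    directions <- directions[!vapply(directions, is.null, logical(1))]
    if (length(directions) != 3L) {
      stop("invalid NRRD header field space directions: ",
           kv[["space directions"]])
    }
    spacing <- vapply(directions, function(v) sqrt(sum(v^2)), numeric(1))
  } else if (!is.null(kv[["spacings"]])) {
    spacing <- as.numeric(strsplit(kv[["spacings"]], "\\s+")[[1L]])[1:3]
  } else {
    stop("NRRD header carries neither 'space directions' nor 'spacings'")
  }
  if (anyNA(spacing) || any(spacing <= 0)) {
    stop("invalid voxel spacing in NRRD header (field ",
         if (is.null(directions)) "spacings" else "space directions",
         "): ", paste(spacing, collapse = " "))
  }
  origin <- c(0, 0, 0)
  if (!is.null(kv[["space origin"]])) {
    o <- parse_nrrd_vectors(kv[["space origin"]])
    if (length(o) == 1L && length(o[[1L]]) == 3L) origin <- o[[1L]]
  }
  endian <- if (is.null(kv[["endian"]])) "little" else kv[["endian"]]
  encoding <- tolower(need("encoding"))
  data_bytes <- bytes[seq.int(hdr_end + 1L, length(bytes))]
  n <- prod(sizes)
  vec <- switch(encoding,
    raw = readBin(data_bytes, tp$what, n = n, size = tp$size,
                  signed = tp$signed, endian = endian),
    gz = ,
    gzip = readBin(memDecompress(data_bytes, type = "gzip"), tp$what, n = n,
                   size = tp$size, signed = tp$signed, endian = endian),
    ascii = ,
    text = ,
    txt = scan(text = rawToChar(data_bytes), what = double(), quiet = TRUE),
    stop("unsupported NRRD encoding: ", encoding)
  )
  if (length(vec) != n) {
    stop("NRRD data stream has ", length(vec), " values, expected ", n)
  }
  arr <- array(vec, dim = sizes) # NRRD lists the fastest axis first, like R
  geometry <- image_geometry(sizes, spacing, origin)
  is_int <- tp$what == "integer" ||
    (encoding %in% c("ascii", "text", "txt") && type %in% names(nrrd_type_table) &&
       nrrd_type_table[[type]]$what == "integer")
  as_label <- switch(kind, auto = is_int, image = FALSE, labelmap = TRUE)
  out <- if (as_label) {
    label_map(arr, geometry = geometry, meaning = auto_meaning(arr))
  } else {
    scalar_volume(arr, geometry = geometry)
  }
  if (!is.null(directions)) attr(out, "space_directions") <- directions
  out
}

auto_meaning <- function(arr) {
  present <- setdiff(sort(unique(as.vector(arr))), 0)
  meaning <- c("1" = "tumor", "2" = "background")
  extra <- setdiff(as.character(as.integer(present)), names(meaning))
  if (length(extra) > 0L) {
    meaning <- c(meaning, stats::setNames(paste0("label_", extra), extra))
  }
  meaning
}

#' Write an NRRD volume
#'
#' Label maps are written losslessly as 32-bit integers, scalar volumes as
#' doubles. Spacing is serialized in mm via axis-aligned `space directions`
#' and the origin via `space origin`.
#'
#' @param v A [scalar_volume()] or [label_map()].
#' @param path Destination `.nrrd` path (parent directory must exist).
#' @param encoding `"raw"` (default), `"gzip"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(v, path, encoding = c("raw", "gzip", "ascii")) {
  encoding <- match.arg(encoding)
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  is_lab <- inherits(v, "label_map")
  if (!is_lab && !inherits(v, "scalar_volume")) {
    stop("v must be a scalar_volume or label_map")
  }
  arr <- if (is_lab) v$labels else v$values
  g <- v$geometry
  hdr <- c(
    "NRRD0004",
    paste0("type: ", if (is_lab) "int" else "double"),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(g$shape, collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            g$spacing[1L], g$spacing[2L], g$spacing[3L]),
    "kinds: domain domain domain",
    if (encoding != "ascii") "endian: little",
    paste0("encoding: ", encoding),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            g$origin[1L], g$origin[2L], g$origin[3L])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  vec <- as.vector(arr)
  size <- if (is_lab) 4L else 8L
  if (encoding == "ascii") {
    writeLines(paste(format(vec, digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = " "), con, sep = "\n")
  } else {
    bytes <- writeBin(vec, raw(), size = size, endian = "little")
    if (encoding == "gzip") bytes <- memCompress(bytes, type = "gzip")
    writeBin(bytes, con)
  }
  invisible(path)
}

#' Read a volume file (NRRD or NIfTI)
#'
#' Dispatches on the file extension: `.nrrd` via [read_nrrd()], `.nii` /
#' `.nii.gz` via RNifti. Integer-typed files load as label maps under
#' `kind = "auto"`.
#'
#' @inheritParams read_nrrd
#' @return A [scalar_volume()] or [label_map()].
#' @export
read_volume <- function(path, kind = c("auto", "image", "labelmap")) {
  kind <- match.arg(kind)
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) return(read_nrrd(path, kind))
  if (grepl("\\.nii(\\.gz)?$", low)) {
    if (!file.exists(path)) stop("file not found: ", path)
    hdr <- RNifti::niftiHeader(path)
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    if (length(dm) != 3L) stop("only 3D NIfTI volumes are supported")
    spacing <- RNifti::pixdim(img)[1:3]
    if (anyNA(spacing) || any(spacing <= 0)) {
      stop("invalid voxel spacing in NIfTI header (field pixdim): ",
           paste(spacing, collapse = " "))
    }
    arr <- array(as.vector(img), dim = dm)
    geometry <- image_geometry(dm, spacing)
    is_int <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
    as_label <- switch(kind, auto = is_int, image = FALSE, labelmap = TRUE)
    if (as_label) {
      return(label_map(arr, geometry = geometry, meaning = auto_meaning(arr)))
    }
    return(scalar_volume(arr, geometry = geometry))
  }
  stop("unsupported volume format: ", path,
       " (supported extensions: .nrrd, .nii, .nii.gz)")
}

#' Write a volume file (NRRD or NIfTI)
#'
#' Dispatches on the file extension. Label maps keep an integer on-disk type
#' in both formats; spacing is serialized in mm.
#'
#' @inheritParams write_nrrd
#' @param ... Passed on to [write_nrrd()] (e.g. `encoding`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, ...) {
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) return(write_nrrd(v, path, ...))
  if (grepl("\\.nii(\\.gz)?$", low)) {
    if (!dir.exists(dirname(path))) {
      stop("parent directory does not exist: ", dirname(path))
    }
    is_lab <- inherits(v, "label_map")
    if (!is_lab && !inherits(v, "scalar_volume")) {
      stop("v must be a scalar_volume or label_map")
    }
    arr <- if (is_lab) v$labels else v$values
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- v$geometry$spacing
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop("unsupported volume format: ", path,
       " (supported extensions: .nrrd, .nii, .nii.gz)")
}

#' Read a case manifest
#'
#' A CSV driving batch evaluation. Three flavors are recognized by their
#' columns:
#' \describe{
#'   \item{evaluation}{`case_id, path_manual, path_auto` — pairs of finished
#'     segmentations to compare}
#'   \item{segmentation}{`case_id, path_image, path_scribbles,
#'     path_reference` — images to segment and evaluate}
#'   \item{records}{the [compare_pair()] columns — precomputed per-case
#'     records, bypassing all image I/O}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return A data frame with attribute `"flavor"`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  flavor <- if (all(c("case_id", "path_manual", "path_auto") %in% names(df))) {
    "evaluation"
  } else if (all(c("case_id", "path_image", "path_scribbles",
                   "path_reference") %in% names(df))) {
    "segmentation"
  } else if (all(case_record_columns %in% names(df))) {
    "records"
  } else {
    stop("unrecognized manifest columns: ", paste(names(df), collapse = ", "))
  }
  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id)) stop("manifest case_ids must be unique")
  base <- dirname(normalizePath(path))
  for (cn in grep("^path_", names(df), value = TRUE)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[cn]])
    df[[cn]][rel] <- file.path(base, df[[cn]][rel])
  }
  attr(df, "flavor") <- flavor
  df
}

#' Run a batch study and write its report
#'
#' Processes every manifest row, assembles the per-case records, and writes
#' `cases.csv`, `summary.csv` and `run_log.txt` into `outdir`. Evaluation
#' rows are compared directly; segmentation rows are segmented with
#' [growcut()], post-edited with `postedit`, and compared against their
#' reference; records rows pass through. A row that fails (unreadable file,
#' invalid scribbles, ...) is recorded and the run continues.
#'
#' The CSV outputs are deterministic: rerunning the same manifest with the
#' same parameters reproduces them byte for byte (the log carries timestamps
#' and is exempt).
#'
#' @param manifest Path to a manifest CSV, or a data frame from
#'   [read_manifest()].
#' @param outdir Output directory (created if missing).
#' @param params [growcut_params()] for segmentation rows.
#' @param postedit List of [postedit_step()]s applied to each GrowCut result
#'   (default: keep-largest island removal only; dilation/erosion are opt-in).
#' @param seed Seed recorded in the log (the pipeline itself is
#'   deterministic; the seed matters only when the manifest was produced by a
#'   seeded generator).
#' @return An object of class `"study_run"`: list with `report` (a
#'   [study_report()] or `NULL` if fewer than 2 rows succeeded), `records`,
#'   `failed` (data frame of failures), `converged` flags, `outdir` and `ok`.
#' @export
run_study <- function(manifest, outdir, params = growcut_params(),
                      postedit = list(postedit_step("remove_islands")),
                      seed = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  flavor <- attr(manifest, "flavor")
  if (is.null(flavor)) stop("manifest lacks a flavor; use read_manifest()")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  records <- NULL
  failed <- data.frame(case_id = character(0), error = character(0),
                       stringsAsFactors = FALSE)
  converged <- logical(0)
  log <- c(sprintf("run_study: %d rows, flavor=%s", nrow(manifest), flavor),
           sprintf("time: %s", format(Sys.time())),
           sprintf("seed: %s", if (is.null(seed)) "none" else seed),
           sprintf("params: neighborhood=%d roi_margin=%d max_iterations=%d max_diff_policy=%s",
                   params$neighborhood, params$roi_margin,
                   params$max_iterations, params$max_diff_policy),
           sprintf("postedit: %s",
                   paste(vapply(postedit, function(s) s$op, character(1)),
                         collapse = " -> ")))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      if (flavor == "records") {
        rec <- row[, case_record_columns]
        conv <- NA
      } else if (flavor == "evaluation") {
        man <- mask_of(read_volume(row$path_manual, "labelmap"), 1L)
        aut <- mask_of(read_volume(row$path_auto, "labelmap"), 1L)
        rec <- compare_pair(man, aut, row$case_id)
        conv <- NA
      } else {
        img <- read_volume(row$path_image, "image")
        scr <- as_scribbles(read_volume(row$path_scribbles, "labelmap"))
        fit <- growcut(img, scr, params, keep_strength = FALSE)
        mask <- apply_postedit(mask_of(fit$label_map, 1L), postedit)
        ref <- mask_of(read_volume(row$path_reference, "labelmap"), 1L)
        rec <- compare_pair(ref, mask, row$case_id)
        conv <- fit$converged
      }
      list(rec = rec, conv = conv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- rbind(failed, data.frame(case_id = row$case_id,
                                         error = conditionMessage(res),
                                         stringsAsFactors = FALSE))
      log <- c(log, sprintf("case %s: FAILED (%s)", row$case_id,
                            conditionMessage(res)))
    } else {
      records <- rbind(records, res$rec)
      converged <- c(converged, res$conv)
      log <- c(log, sprintf("case %s: ok%s", row$case_id,
                            if (is.na(res$conv)) "" else
                              if (res$conv) ", converged" else ", NOT converged"))
    }
  }
  report <- NULL
  if (!is.null(records)) {
    utils::write.csv(records, file.path(outdir, "cases.csv"),
                     row.names = FALSE)
    if (nrow(records) >= 2L) {
      report <- study_report(records)
      utils::write.csv(report$summary, file.path(outdir, "summary.csv"),
                       row.names = FALSE)
    }
  }
  writeLines(log, file.path(outdir, "run_log.txt"))
  structure(list(report = report, records = records, failed = failed,
                 converged = converged, outdir = outdir,
                 ok = nrow(failed) == 0L),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  n_ok <- if (is.null(x$records)) 0L else nrow(x$records)
  cat(sprintf("Study run: %d cases ok, %d failed; outputs in %s\n",
              n_ok, nrow(x$failed), x$outdir))
  if (nrow(x$failed) > 0L) {
    print(x$failed, row.names = FALSE)
  }
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Read a post-edit sequence from a YAML config file
#'
#' The file holds a top-level `postedit:` list of steps, each a mapping with
#' `op` and the relevant options, e.g.
#' ```yaml
#' postedit:
#'   - op: remove_islands
#'     min_size: keep_largest
#'   - op: dilate
#'     radius: 1
#'     connectivity: 6
#' ```
#'
#' @param path YAML file path.
#' @return A list of [postedit_step()] objects.
#' @export
read_postedit_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  steps <- cfg$postedit
  if (is.null(steps)) stop("config has no top-level 'postedit' list")
  lapply(steps, function(s) {
    postedit_step(op = s$op,
                  radius = if (is.null(s$radius)) 1L else s$radius,
                  connectivity = if (is.null(s$connectivity)) 26L
                                 else s$connectivity,
                  min_size = if (is.null(s$min_size)) "keep_largest"
                             else s$min_size)
  })
}
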