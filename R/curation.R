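# Dataset curation: class-root discovery, label canonicalization,
# average-hash near-duplicate removal, seeded stratified splitting.

#' The four canonical tumor classes, in index order
#' @export
CANONICAL_CLASSES <- c("glioma", "meningioma", "no_tumor", "pituitary")

# synonym table applied after lowercasing and separator stripping
.LABEL_SYNONYMS <- c(
  glioma = "glioma", gliomatumor = "glioma",
  meningioma = "meningioma", meningiomatumor = "meningioma",
  notumor = "no_tumor", notumour = "no_tumor", healthy = "no_tumor",
  normal = "no_tumor",
  pituitary = "pituitary", pituitarytumor = "pituitary"
)

.IMAGE_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Locate the class-folder root of an image dataset
#'
#' Probes a prioritized candidate list — the root itself, then known
#' `Training/` / `Testing/` containers (case-insensitive), then the
#' first-level children in lexicographic order — and returns the first
#' candidate holding at least two subdirectories.
#'
#' @param root Directory to probe.
#' @return Path of the discovered class root.
#' @export
discover_class_root <- function(root) {
  if (!dir.exists(root)) stop("root does not exist: ", root)
  kids <- function(p) sort(list.dirs(p, recursive = FALSE, full.names = TRUE))
  children <- kids(root)
  containers <- children[tolower(basename(children)) %in% c("training", "testing")]
  candidates <- c(root, containers, setdiff(children, containers))
  for (p in candidates) if (length(kids(p)) >= 2L) return(p)
  stop("no class root found (need >= 2 subdirectories); probed: ",
       paste(candidates, collapse = ", "))
}

#' Canonicalize a class-folder name
#'
#' Lowercases, strips separators and maps through the synonym table to
#' one of `glioma`, `meningioma`, `no_tumor`, `pituitary`. Idempotent on
#' canonical labels.
#'
#' @param raw Folder name.
#' @return Canonical class string.
#' @export
#' @examples
#' canonicalize_label("glioma_tumor")
#' canonicalize_label("no_tumour")
canonicalize_label <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  key <- gsub("[^a-z0-9]", "", tolower(raw))
  if (!key %in% names(.LABEL_SYNONYMS))
    stop("unknown class '", raw, "'; known synonyms: ",
         paste(names(.LABEL_SYNONYMS), collapse = ", "))
  unname(.LABEL_SYNONYMS[key])
}

#' Average-hash fingerprint of an image
#'
#' Computes the 64-bit aHash: BT.601 grayscale, bilinear 8 x 8
#' thumbnail, strict thresholding at the thumbnail mean
#' (`b_uv = 1 if G_uv > mean else 0`), row-major flattening. The hash is
#' packed into 8 bytes (MSB-first within each byte) and digested with
#' SHA-1 to give a portable dedup key; a constant image therefore hashes
#' to all-zero bits.
#'
#' @param image H x W or H x W x 3 array in \[0, 1\].
#' @return List with `bits` (integer vector of 64 zeros/ones) and `key`
#'   (40-char SHA-1 hex digest).
#' @export
compute_ahash <- function(image) {
  g <- resize_bilinear(rgb_to_gray(image), 8L, 8L)
  mu <- mean(g)
  bits <- as.integer(t(g) > mu)  # row-major flattening
  bytes <- raw(8)
  for (i in 1:8) {
    b <- bits[(i - 1) * 8 + 1:8]
    bytes[i] <- as.raw(sum(b * 2^(7:0)))
  }
  list(bits = bits, key = sha1_hex(bytes))
}

# build an ImageRecord data.frame row; returns NULL (with a warning)
# when the file cannot be decoded
.image_record <- function(path, raw_label) {
  img <- tryCatch(read_image(path), error = function(e) NULL)
  if (is.null(img)) {
    warning("skipping undecodable image: ", path, call. = FALSE)
    return(NULL)
  }
  h <- compute_ahash(img)
  data.frame(path = path, raw_label = raw_label,
             label = canonicalize_label(raw_label),
             ahash_key = h$key,
             width = dim(img)[2], height = dim(img)[1],
             stringsAsFactors = FALSE)
}

#' Scan a class root into a table of image records
#'
#' Walks each class subdirectory (lexicographic order), canonicalizes
#' its name, decodes each image and attaches its aHash key. Undecodable
#' files are skipped with a warning.
#'
#' @param class_root Directory whose subdirectories are class folders.
#' @return `data.frame` with columns `path`, `raw_label`, `label`,
#'   `ahash_key`, `width`, `height`.
#' @export
scan_class_root <- function(class_root) {
  dirs <- sort(list.dirs(class_root, recursive = FALSE, full.names = TRUE))
  rows <- list()
  for (d in dirs) {
    files <- sort(list.files(d, full.names = TRUE))
    files <- files[tolower(tools::file_ext(files)) %in% .IMAGE_EXT]
    for (f in files) {
      r <- .image_record(f, basename(d))
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows))
    return(data.frame(path = character(), raw_label = character(),
                      label = character(), ahash_key = character(),
                      width = integer(), height = integer()))
  do.call(rbind, rows)
}

#' Remove per-class near-duplicates by aHash key
#'
#' Within each canonical class, records are visited in sorted-path
#' order and only the first record per aHash key is kept. Keys are
#' scoped per class: identical keys in different classes both survive.
#' Idempotent.
#'
#' @param records Record `data.frame` from [scan_class_root()].
#' @return Deduplicated record `data.frame`.
#' @export
dedup_per_class <- function(records) {
  if (!nrow(records)) return(records)
  records <- records[order(records$path), , drop = FALSE]
  keep <- !duplicated(paste(records$label, records$ahash_key, sep = "/"))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seeded stratified train/validation split
#'
#' Per class, paths are sorted, shuffled by a seeded generator, and the
#' first `round(val_fraction * n)` (round-half-up; at least 1 when
#' `n >= 2`) records go to validation, the rest to training. A class
#' with a single record goes entirely to training with a warning.
#'
#' @param records Deduplicated record `data.frame`.
#' @param val_fraction Validation proportion in (0, 1).
#' @param seed Integer seed; identical inputs reproduce the split.
#' @param test Optional record `data.frame` of a predefined held-out
#'   test container, passed through untouched.
#' @return A `split_manifest` list with elements `train`, `val`, `test`
#'   (record data.frames), `seed`, `val_fraction`, `class_counts`.
#' @export
stratified_split <- function(records, val_fraction, seed, test = NULL) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  if (!nrow(records)) stop("no records to split")
  if (any(!records$label %in% CANONICAL_CLASSES)) stop("non-canonical label in records")
  classes <- sort(unique(records$label))
  tr <- list(); va <- list()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    rc <- records[records$label == cl, , drop = FALSE]
    rc <- rc[order(rc$path), , drop = FALSE]
    n <- nrow(rc)
    if (n == 0L) stop("class with 0 records: ", cl)
    if (n == 1L) {
      warning("class '", cl, "' has a single record; assigning to train")
      tr[[cl]] <- rc
      next
    }
    n_val <- max(1L, as.integer(round_half_up(val_fraction * n)))
    # per-class derived seed keeps the split invariant to class ordering
    perm <- with_seed(seed + k, sample.int(n))
    va[[cl]] <- rc[perm[seq_len(n_val)], , drop = FALSE]
    tr[[cl]] <- rc[perm[(n_val + 1L):n], , drop = FALSE]
  }
  train <- do.call(rbind, tr); rownames(train) <- NULL
  val <- if (length(va)) do.call(rbind, va) else records[0, , drop = FALSE]
  rownames(val) <- NULL
  if (is.null(test)) test <- records[0, , drop = FALSE]
  counts <- function(df) {
    tb <- table(factor(df$label, levels = CANONICAL_CLASSES))
    as.list(stats::setNames(as.integer(tb), names(tb)))
  }
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 class_counts = list(train = counts(train), val = counts(val),
                                     test = counts(test))),
            class = "split_manifest")
}

#' Curate an image dataset directory into a split manifest
#'
#' End-to-end curation: discovers the class root, treats a predefined
#' `Testing/` container (case-insensitive) as the held-out test set,
#' scans and canonicalizes records, removes per-class near-duplicates
#' within each container, and performs the seeded stratified split on
#' the training portion.
#'
#' @param root Dataset directory.
#' @param val_fraction Validation proportion (default 0.1).
#' @param seed Integer seed (default 42).
#' @return A `split_manifest`; see [stratified_split()].
#' @export
curate <- function(root, val_fraction = 0.1, seed = 42L) {
  children <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  test_dir <- children[tolower(basename(children)) == "testing"]
  train_dir <- children[tolower(basename(children)) == "training"]
  train_root <- if (length(train_dir)) discover_class_root(train_dir[1])
                else discover_class_root(root)
  if (length(test_dir) && normalizePath(train_root) == normalizePath(test_dir[1]))
    stop("only a Testing/ container was found; no training data")
  train_records <- dedup_per_class(scan_class_root(train_root))
  test_records <- NULL
  if (length(test_dir))
    test_records <- dedup_per_class(scan_class_root(test_dir[1]))
  stratified_split(train_records, val_fraction, seed, test = test_records)
}

#' Write a split manifest to JSON
#'
#' @param manifest A `split_manifest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(seed = manifest$seed, val_fraction = manifest$val_fraction,
         class_counts = manifest$class_counts,
         splits = list(train = manifest$train, val = manifest$val,
                       test = manifest$test)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a split manifest from JSON
#'
#' @param path Manifest JSON path written by [write_manifest()].
#' @return A `split_manifest`.
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(df) {
    if (is.null(df) || !length(df))
      return(data.frame(path = character(), raw_label = character(),
                        label = character(), ahash_key = character(),
                        width = integer(), height = integer()))
    df$width <- as.integer(df$width); df$height <- as.integer(df$height)
    df
  }
  structure(list(train = fix(j$splits$train), val = fix(j$splits$val),
                 test = fix(j$splits$test), seed = as.integer(j$seed),
                 val_fraction = j$val_fraction, class_counts = j$class_counts),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("Split manifest (seed ", x$seed, ", val fraction ", x$val_fraction, ")\n", sep = "")
  for (s in c("train", "val", "test")) {
    cc <- unlist(x$class_counts[[s]])
    cat(sprintf("  %-5s n=%4d  [%s]\n", s, nrow(x[[s]]),
                paste(names(cc), cc, sep = "=", collapse = ", ")))
  }
  invisible(x)
}
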