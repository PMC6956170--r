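MODEL_SCHEMA_VERSION <- "1"

#' Read a delimited tabular dataset
#'
#' Parses a UCI-style delimited text file (one row per sample, numeric
#' feature columns, one label column) into a [labeled_dataset()]. Rows
#' containing non-numeric or non-finite feature values are dropped with a
#' logged count.
#'
#' @param path Path to the file.
#' @param label_col Name of the label column.
#' @param delimiter Field separator (comma by default; tab accepted).
#' @return A [labeled_dataset()].
#' @export
read_tabular <- function(path, label_col, delimiter = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_col %in% names(df)) {
    stop(sprintf("label column '%s' not found; columns: %s", label_col,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  y <- as.character(df[[label_col]])
  feats <- df[setdiff(names(df), label_col)]
  X <- vapply(feats, function(col) {
    suppressWarnings(as.numeric(as.character(col)))
  }, numeric(nrow(df)))
  X <- matrix(X, nrow = nrow(df),
              dimnames = list(NULL, setdiff(names(df), label_col)))
  ok <- apply(X, 1L, function(r) all(is.finite(r)))
  if (sum(!ok) > 0L) {
    message(sprintf("read_tabular: dropped %d row(s) with non-numeric or non-finite features",
                    sum(!ok)))
  }
  if (sum(ok) == 0L) {
    stop(sprintf("no usable rows in %s after dropping non-numeric features",
                 path), call. = FALSE)
  }
  ds <- labeled_dataset(X[ok, , drop = FALSE], y[ok])
  message(sprintf("read_tabular: %d samples, %d features, classes: %s",
                  nrow(ds$X), ncol(ds$X), paste(ds$classes, collapse = ", ")))
  ds
}

#' @rdname read_tabular
#' @param ds A [labeled_dataset()] to write.
#' @export
write_tabular <- function(ds, path, label_col = "label", delimiter = ",") {
  ds <- as_labeled_dataset(ds)
  X <- ds$X
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  df[[label_col]] <- ds$y
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a signal recording
#'
#' Recordings are stored as delimited text with one column per channel
#' (header row = channel names, one row per sample) plus a JSON sidecar
#' holding the sampling rate and run-length encoded annotations
#' (`[label, start_sample, end_sample]`, 1-based inclusive).
#'
#' @param path Path to the delimited signal file.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with a
#'   `.json` extension.
#' @param delimiter Field separator.
#' @return A [signal_recording()].
#' @export
read_recording <- function(path, sidecar = NULL, delimiter = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("sidecar not found: %s", sidecar), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE)
  side <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  n <- nrow(df)
  ann <- NULL
  if (!is.null(side$annotations)) {
    ann <- rep(NA_character_, n)
    for (run in side$annotations) {
      ann[as.integer(run[[2L]]):as.integer(run[[3L]])] <- as.character(run[[1L]])
    }
  }
  side$rate_hz <- as.numeric(side$rate_hz)
  signal_recording(t(as.matrix(df)), side$rate_hz,
                   channel_names = names(df), annotations = ann)
}

#' @rdname read_recording
#' @param rec A [signal_recording()] to write.
#' @export
write_recording <- function(rec, path, sidecar = NULL, delimiter = ",") {
  stopifnot(inherits(rec, "signal_recording"))
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  runs <- NULL
  if (!is.null(rec$annotations)) {
    r <- rle(rec$annotations)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- lapply(seq_along(r$values), function(i) {
      list(r$values[i], starts[i], ends[i])
    })
  }
  jsonlite::write_json(list(rate_hz = rec$rate, annotations = runs),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

kernel_to_list <- function(k) {
  if (is.null(k)) return(NULL)
  list(kind = k$kind, gamma = k$gamma, degree = k$degree, coef0 = k$coef0)
}

kernel_from_list <- function(l) {
  if (is.null(l) || length(l) == 0L) return(NULL)
  kernel_spec(l$kind, gamma = l$gamma, degree = l$degree, coef0 = l$coef0)
}

svm_to_list <- function(m) {
  list(variant = m$variant, kernel = kernel_to_list(m$kernel),
       cost = if (is.null(m$cost)) NA else m$cost,
       nu = if (is.null(m$nu)) NA else m$nu,
       classes = m$classes, dim = m$dim,
       multiclass_scheme = m$multiclass_scheme,
       pairs = lapply(m$pairs, function(p) {
         list(pos = p$pos, neg = p$neg, sv = p$sv,
              coefs = p$coefs, rho = p$rho)
       }))
}

as_matrix_cols <- function(x, ncols) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = ncols, byrow = TRUE)
  as.matrix(x)
}

drop_missing <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
}

svm_from_list <- function(l) {
  structure(
    list(variant = l$variant, kernel = kernel_from_list(l$kernel),
         cost = drop_missing(l$cost),
         nu = drop_missing(l$nu),
         classes = as.character(l$classes), dim = as.integer(l$dim),
         multiclass_scheme = l$multiclass_scheme,
         pairs = lapply(l$pairs, function(p) {
           list(pos = p$pos, neg = p$neg,
                sv = as_matrix_cols(p$sv, l$dim),
                coefs = as.numeric(p$coefs), rho = as.numeric(p$rho))
         })),
    class = "svm_fit"
  )
}

#' Save / load a model as JSON
#'
#' Serializes a fitted `svm_fit` or `advised_fit` to a single JSON
#' document carrying the kernel spec, per-pair support vectors, signed
#' dual coefficients, biases and class order — enough to recompute
#' decision values independently of the training backend. Advised models
#' additionally carry the advising block (space, misclassified rows with
#' their neighborhood lengths, normalization tag, and for the label space
#' the encoding table and label-kernel spec). Round-tripping reproduces
#' decision values to well below 1e-9.
#'
#' @param model An `svm_fit` or `advised_fit`.
#' @param path Destination / source path.
#' @return `load_model()` returns the reconstructed model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "svm_fit")) {
    doc <- c(list(schema_version = MODEL_SCHEMA_VERSION, type = "svm_fit"),
             svm_to_list(model))
  } else if (inherits(model, "advised_fit")) {
    doc <- list(
      schema_version = MODEL_SCHEMA_VERSION, type = "advised_fit",
      base = svm_to_list(model$base),
      advising = list(
        space = model$space, normalization = model$normalization,
        md = list(indices = model$md$indices, points = model$md$points,
                  labels = model$md$labels, nl = model$md$nl),
        encoding = if (is.null(model$encoding)) NULL else
          list(scheme = model$encoding$scheme,
               classes = model$encoding$classes,
               mapping = unname(model$encoding$mapping)),
        label_kernel = kernel_to_list(model$label_kernel)
      )
    )
  } else {
    stop("`model` must be an svm_fit or advised_fit", call. = FALSE)
  }
  # 17 significant digits: exact IEEE-double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop(sprintf("not a valid model file (%s): %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.null(doc$schema_version)) {
    stop("not a valid model file: missing schema_version", call. = FALSE)
  }
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version '%s' is not supported (expected '%s')",
                 doc$schema_version, MODEL_SCHEMA_VERSION), call. = FALSE)
  }
  if (identical(doc$type, "svm_fit")) return(svm_from_list(doc))
  if (!identical(doc$type, "advised_fit")) {
    stop(sprintf("unknown model type '%s'", doc$type), call. = FALSE)
  }
  base <- svm_from_list(doc$base)
  adv <- doc$advising
  nmd <- length(unlist(adv$md$indices))
  na_numeric <- function(x, n) {
    if (is.list(x)) {
      vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    } else if (length(x) == 0L) {
      rep(NA_real_, n)
    } else {
      as.numeric(x)
    }
  }
  md <- structure(
    list(indices = as.integer(unlist(adv$md$indices)),
         points = if (nmd == 0L) {
           matrix(numeric(0), 0L, base$dim)
         } else {
           as_matrix_cols(adv$md$points, base$dim)
         },
         labels = as.character(unlist(adv$md$labels)),
         nl = na_numeric(adv$md$nl, nmd)),
    class = "misclassified_set"
  )
  enc <- NULL
  if (!is.null(adv$encoding)) {
    classes <- as.character(unlist(adv$encoding$classes))
    mapping <- as_matrix_cols(adv$encoding$mapping,
                              if (identical(adv$encoding$scheme, "one_hot"))
                                length(classes) else 1L)
    rownames(mapping) <- classes
    enc <- structure(list(scheme = adv$encoding$scheme,
                          classes = classes, mapping = mapping),
                     class = "label_encoding")
  }
  structure(
    list(base = base, md = md, space = adv$space,
         normalization = adv$normalization, encoding = enc,
         label_kernel = kernel_from_list(adv$label_kernel)),
    class = "advised_fit"
  )
}
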