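#' Save a fitted forest as JSON
#'
#' The schema (version 1) stores the config, resolved `m_try`, feature
#' names, class order, per-tree flat node arrays and per-tree bootstrap
#' indices, so a reloaded forest reproduces predictions and out-of-bag
#' computations exactly. Leaf nodes are marked by `feature = 0`.
#'
#' @param forest an [rf_fit()] result.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
rf_save <- function(forest, path) {
  stopifnot(inherits(forest, "aeeg_forest"))
  enc_tree <- function(tr) {
    f <- tr$feature
    th <- tr$threshold
    f[is.na(f)] <- 0L
    th[is.na(th)] <- 0
    list(feature = f, threshold = th, left = tr$left, right = tr$right,
         prob_abnormal = tr$prob[, 1L], prob_normal = tr$prob[, 2L])
  }
  obj <- list(
    format = "aeegrf-forest",
    version = 1L,
    package_version = as.character(utils::packageVersion("aeegrf")),
    config = list(n_tree = forest$config$n_tree,
                  class_weights = as.list(forest$config$class_weights),
                  seed = forest$config$seed,
                  min_leaf = forest$config$min_leaf,
                  vote_mode = forest$config$vote_mode),
    m_try = forest$m_try,
    n_train = forest$n_train,
    feature_names = forest$feature_names,
    classes = forest$classes,
    trees = lapply(forest$trees, enc_tree),
    inbag = forest$inbag
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a forest saved by [rf_save()]
#'
#' @param path `.json` path.
#' @return an `aeeg_forest` giving predictions identical to the saved one.
#' @export
rf_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "aeegrf-forest")) {
    stop("not an aeegrf forest file: ", path)
  }
  if (obj$version != 1L) stop("unsupported forest schema version ", obj$version)
  dec_tree <- function(tr) {
    f <- as.integer(tr$feature)
    th <- as.numeric(tr$threshold)
    th[f == 0L] <- NA_real_
    f[f == 0L] <- NA_integer_
    list(feature = f, threshold = th,
         left = as.integer(tr$left), right = as.integer(tr$right),
         prob = cbind(as.numeric(tr$prob_abnormal),
                      as.numeric(tr$prob_normal)))
  }
  trees <- if (is.data.frame(obj$trees)) {
    lapply(seq_len(nrow(obj$trees)), function(i) {
      dec_tree(lapply(obj$trees, function(col) col[[i]]))
    })
  } else {
    lapply(obj$trees, dec_tree)
  }
  cw <- unlist(obj$config$class_weights)
  config <- forest_config(n_tree = obj$config$n_tree,
                          m_try = obj$m_try,
                          class_weights = cw,
                          seed = obj$config$seed,
                          min_leaf = obj$config$min_leaf,
                          vote_mode = obj$config$vote_mode)
  structure(
    list(trees = trees,
         inbag = if (is.matrix(obj$inbag)) {
           lapply(seq_len(nrow(obj$inbag)), function(i) {
             as.integer(obj$inbag[i, ])
           })
         } else {
           lapply(obj$inbag, as.integer)
         },
         config = config, m_try = as.integer(obj$m_try),
         feature_names = obj$feature_names, classes = obj$classes,
         n_train = as.integer(obj$n_train)),
    class = "aeeg_forest"
  )
}
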