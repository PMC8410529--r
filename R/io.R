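## Plain-format IO: multichannel TIFF + channel-role YAML sidecar for
## stacks, CSV for cell tables and calls, YAML snapshots of gating
## configs for audit.

#' Read / write a ChannelStack as multichannel TIFF plus YAML sidecar
#'
#' The stack is written as a multi-page 32-bit float TIFF (one page per
#' channel). TIFF float pages store values in \[0, 1\], so intensities are
#' scaled by the stack maximum, which is recorded in the YAML sidecar
#' together with the page-order role map and restored on read.
#'
#' @param stack A [ChannelStack-class].
#' @param tiffPath Path of the TIFF file.
#' @param rolesPath Path of the YAML sidecar (default `<tiffPath>.yml`).
#' @return `writeChannelStack()`: the paths, invisibly;
#'   `readChannelStack()`: a [ChannelStack-class].
#' @export
writeChannelStack <- function(stack, tiffPath,
                              rolesPath = paste0(tiffPath, ".yml")) {
  stopifnot(is(stack, "ChannelStack"))
  scale <- max(1, max(vapply(stackRoles(stack),
                             function(r) max(getChannel(stack, r)),
                             numeric(1))))
  pages <- lapply(stackRoles(stack),
                  function(r) getChannel(stack, r) / scale)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L)
  yaml::write_yaml(list(roles = stackRoles(stack), scale = scale),
                   rolesPath)
  invisible(c(tiff = tiffPath, roles = rolesPath))
}

#' @rdname writeChannelStack
#' @export
readChannelStack <- function(tiffPath, rolesPath = paste0(tiffPath, ".yml")) {
  side <- yaml::read_yaml(rolesPath)
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (length(pages) != length(side$roles)) {
    stop("TIFF page count does not match the sidecar role map")
  }
  chans <- lapply(pages, function(p) p * side$scale)
  names(chans) <- side$roles
  ChannelStack(chans)
}

#' Read / write cell tables and phenotype calls as CSV
#'
#' `writeCellTable()` drops the hidden `truth_` columns of simulated
#' tables unless `includeTruth = TRUE`, so ground truth never enters the
#' analysis-facing schema.
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @param includeTruth Keep `truth_` columns (test use only).
#' @return `writeCellTable()`: `path`, invisibly; `readCellTable()`: a
#'   data.frame.
#' @export
writeCellTable <- function(x, path, includeTruth = FALSE) {
  if (!includeTruth) x <- stripTruth(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a GatingConfig snapshot as YAML
#'
#' Audit snapshot of the cutoffs, derivation method and rule-set version
#' used for a sample.
#'
#' @param config A [GatingConfig-class].
#' @param path YAML path.
#' @return `writeGatingConfig()`: `path`, invisibly;
#'   `readGatingConfig()`: a [GatingConfig-class].
#' @export
writeGatingConfig <- function(config, path) {
  stopifnot(is(config, "GatingConfig"))
  yaml::write_yaml(list(cutoffs = as.list(gatingCutoffs(config)),
                        method = config@method,
                        rulesVersion = config@rulesVersion), path)
  invisible(path)
}

#' @rdname writeGatingConfig
#' @export
readGatingConfig <- function(path) {
  x <- yaml::read_yaml(path)
  GatingConfig(unlist(x$cutoffs), method = x$method,
               rulesVersion = x$rulesVersion)
}
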