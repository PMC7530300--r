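#' Read an annotated 12-lead ECG record
#'
#' Loads one record from disk, in one of three supported formats, and returns
#' an [annotated_ecg()] normalised to 500 Hz (records at other sampling
#' frequencies are resampled and annotation indices rescaled).
#'
#' Formats:
#' \describe{
#'   \item{`wfdb`}{`path` is the record name (no extension). Expects
#'     `<path>.hea` (text header), `<path>.dat` (format 16, 16-bit
#'     little-endian, interleaved, gain in adu/mV) and the plain-text
#'     annotation sidecar `<path>.ann.csv` with columns
#'     `beat,p_on,q_on,j_point,t_end` in milliseconds. This is a documented
#'     subset of the WFDB conventions; binary WFDB annotation files are not
#'     supported.}
#'   \item{`aecg`}{`path` is an XML file using a subset of the HL7 aECG
#'     structure: one `series` of `sequence` elements (a time sequence with
#'     sampling increment, one amplitude sequence per lead in microvolt
#'     digits with scale/origin) plus `beatAnnotations` carrying the P onset,
#'     Q onset, J point and T end times in milliseconds.}
#'   \item{`csv`}{`path` is a long-format table `sample,lead,amplitude_mV`
#'     with a `# fs: <Hz>` comment header; annotations live in the sidecar
#'     `<stem>_annotations.csv` (`beat,p_on,q_on,j_point,t_end`, ms).}
#' }
#'
#' @param path Record path (see Details per format).
#' @param format One of `"wfdb"`, `"aecg"`, `"csv"`.
#' @param meta Named list of study metadata attached to the record.
#' @return An `annotated_ecg` at 500 Hz.
#' @export
load_annotated_ecg <- function(path, format = c("wfdb", "aecg", "csv"), meta = list()) {
  format <- match.arg(format)
  ecg <- switch(format,
    wfdb = read_wfdb_record(path, meta),
    aecg = read_aecg_xml(path, meta),
    csv  = read_ecg_csv(path, meta)
  )
  resample_ecg(ecg, 500)
}

#' Write an annotated ECG record
#'
#' Counterpart of [load_annotated_ecg()]; writes the record in the requested
#' format (see that help page for the on-disk layouts).
#'
#' @param ecg An `annotated_ecg`.
#' @param path Record path (for `wfdb`, the record name without extension).
#' @param format One of `"wfdb"`, `"aecg"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_annotated_ecg <- function(ecg, path, format = c("wfdb", "aecg", "csv")) {
  format <- match.arg(format)
  switch(format,
    wfdb = write_wfdb_record(ecg, path),
    aecg = write_aecg_xml(ecg, path),
    csv  = write_ecg_csv(ecg, path)
  )
  invisible(path)
}

## ---- WFDB subset (format 16) ------------------------------------------------

WFDB_GAIN <- 1000  # adu per mV, i.e. 1 uV amplitude resolution

write_wfdb_record <- function(ecg, record) {
  rec_name <- basename(record)
  n <- nrow(ecg$signal); nsig <- ncol(ecg$signal)
  hea <- c(
    sprintf("%s %d %g %d", rec_name, nsig, ecg$fs, n),
    sprintf("%s.dat 16 %d/mV 16 0 0 0 0 %s", rec_name, WFDB_GAIN, colnames(ecg$signal))
  )
  writeLines(hea, paste0(record, ".hea"))
  adu <- round(ecg$signal * WFDB_GAIN)
  adu <- pmin(pmax(adu, -32768), 32767)
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adu)), con, size = 2L, endian = "little")
  ann <- ecg$beats[, c("p_on", "q_on", "j_point", "t_end")] * 1000 / ecg$fs
  ann <- cbind(beat = seq_len(nrow(ann)), ann)
  utils::write.csv(ann, paste0(record, ".ann.csv"), row.names = FALSE)
}

read_wfdb_record <- function(record, meta = list()) {
  hea_path <- paste0(record, ".hea")
  if (!file.exists(hea_path)) stop("unparseable or missing WFDB header: ", hea_path)
  hea <- readLines(hea_path)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(n)) stop("unparseable WFDB header: ", hea_path)
  leads <- character(nsig); gains <- numeric(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(hea[1 + i]), "\\s+")[[1]]
    gains[i] <- as.numeric(sub("/.*$", "", f[3]))
    leads[i] <- f[length(f)]
  }
  con <- file(paste0(record, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n * nsig, size = 2L, endian = "little", signed = TRUE)
  sig <- matrix(raw, ncol = nsig, byrow = TRUE)
  sig <- sweep(sig, 2, gains, "/")
  colnames(sig) <- leads
  ann_path <- paste0(record, ".ann.csv")
  beats <- if (file.exists(ann_path)) {
    a <- utils::read.csv(ann_path)
    data.frame(p_on = round(a$p_on * fs / 1000), q_on = round(a$q_on * fs / 1000),
               j_point = round(a$j_point * fs / 1000), t_end = round(a$t_end * fs / 1000))
  } else {
    data.frame(p_on = numeric(0), q_on = numeric(0), j_point = numeric(0), t_end = numeric(0))
  }
  annotated_ecg(sig, fs, beats, meta)
}

## ---- HL7 aECG subset --------------------------------------------------------

AECG_CODES <- c(p_on = "MDC_ECG_WAVC_PWAVE", q_on = "MDC_ECG_WAVC_QRSWAVE",
                j_point = "MDC_ECG_WAVC_JPOINT", t_end = "MDC_ECG_WAVC_TWAVE_END")

write_aecg_xml <- function(ecg, path) {
  doc <- xml2::xml_new_root("AnnotatedECG", xmlns = "urn:hl7-org:v3")
  series <- xml2::xml_add_child(xml2::xml_add_child(doc, "component"), "series")
  sset <- xml2::xml_add_child(xml2::xml_add_child(series, "component"), "sequenceSet")
  tseq <- xml2::xml_add_child(xml2::xml_add_child(sset, "component"), "sequence")
  xml2::xml_add_child(tseq, "code", code = "TIME_ABSOLUTE")
  tval <- xml2::xml_add_child(tseq, "value")
  xml2::xml_add_child(tval, "head", value = "0", unit = "s")
  xml2::xml_add_child(tval, "increment", value = format(1 / ecg$fs, digits = 12), unit = "s")
  for (lead in colnames(ecg$signal)) {
    lseq <- xml2::xml_add_child(xml2::xml_add_child(sset, "component"), "sequence")
    xml2::xml_add_child(lseq, "code", code = paste0("MDC_ECG_LEAD_", lead))
    lval <- xml2::xml_add_child(lseq, "value")
    xml2::xml_add_child(lval, "origin", value = "0", unit = "uV")
    xml2::xml_add_child(lval, "scale", value = "1", unit = "uV")
    digits <- paste(format(round(ecg$signal[, lead] * 1000), scientific = FALSE, trim = TRUE),
                    collapse = " ")
    xml2::xml_add_child(lval, "digits", digits)
  }
  anns <- xml2::xml_add_child(series, "beatAnnotations")
  for (b in seq_len(nrow(ecg$beats))) {
    bt <- xml2::xml_add_child(anns, "beat", index = as.character(b))
    for (fid in names(AECG_CODES)) {
      v <- ecg$beats[[fid]][b]
      if (!is.na(v)) {
        xml2::xml_add_child(bt, "annotation", code = AECG_CODES[[fid]],
                            value = format(v * 1000 / ecg$fs, digits = 12), unit = "ms")
      }
    }
  }
  xml2::write_xml(doc, path)
}

read_aecg_xml <- function(path, meta = list()) {
  if (!file.exists(path)) stop("missing aECG file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) stop("unparseable aECG file: ", path))
  ns <- c(h = "urn:hl7-org:v3")
  seqs <- xml2::xml_find_all(doc, ".//h:sequenceSet/h:component/h:sequence", ns)
  fs <- NA_real_; leads <- list()
  for (sq in seqs) {
    code <- xml2::xml_attr(xml2::xml_find_first(sq, "./h:code", ns), "code")
    if (identical(code, "TIME_ABSOLUTE")) {
      inc <- as.numeric(xml2::xml_attr(xml2::xml_find_first(sq, ".//h:increment", ns), "value"))
      fs <- 1 / inc
    } else if (startsWith(code, "MDC_ECG_LEAD_")) {
      lead <- sub("^MDC_ECG_LEAD_", "", code)
      val <- xml2::xml_find_first(sq, "./h:value", ns)
      scale <- as.numeric(xml2::xml_attr(xml2::xml_find_first(val, "./h:scale", ns), "value"))
      origin <- as.numeric(xml2::xml_attr(xml2::xml_find_first(val, "./h:origin", ns), "value"))
      digits <- scan(text = xml2::xml_text(xml2::xml_find_first(val, "./h:digits", ns)),
                     quiet = TRUE)
      leads[[lead]] <- (origin + scale * digits) / 1000  # uV -> mV
    }
  }
  if (is.na(fs)) stop("aECG file lacks a TIME_ABSOLUTE sequence: ", path)
  sig <- do.call(cbind, leads)
  beat_nodes <- xml2::xml_find_all(doc, ".//h:beatAnnotations/h:beat", ns)
  beats <- data.frame(p_on = NA_real_, q_on = NA_real_, j_point = NA_real_,
                      t_end = NA_real_)[rep(1, length(beat_nodes)), , drop = FALSE]
  for (b in seq_along(beat_nodes)) {
    for (fid in names(AECG_CODES)) {
      node <- xml2::xml_find_first(
        beat_nodes[[b]], sprintf("./h:annotation[@code='%s']", AECG_CODES[[fid]]), ns)
      if (!inherits(node, "xml_missing")) {
        beats[[fid]][b] <- round(as.numeric(xml2::xml_attr(node, "value")) * fs / 1000)
      }
    }
  }
  annotated_ecg(sig, fs, beats, meta)
}

## ---- internal CSV dialect ---------------------------------------------------

csv_annotation_path <- function(path) sub("\\.csv$", "_annotations.csv", path)

write_ecg_csv <- function(ecg, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs: %g", ecg$fs), con)
  long <- data.frame(
    sample = rep(seq_len(nrow(ecg$signal)) - 1L, times = ncol(ecg$signal)),
    lead = rep(colnames(ecg$signal), each = nrow(ecg$signal)),
    amplitude_mV = as.vector(ecg$signal)
  )
  utils::write.csv(long, con, row.names = FALSE)
  close(con)
  ann <- ecg$beats[, c("p_on", "q_on", "j_point", "t_end")] * 1000 / ecg$fs
  utils::write.csv(cbind(beat = seq_len(nrow(ann)), ann),
                   csv_annotation_path(path), row.names = FALSE)
}

read_ecg_csv <- function(path, meta = list()) {
  if (!file.exists(path)) stop("missing ECG csv: ", path)
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub("^#\\s*fs:\\s*", "", hdr))
  if (is.na(fs)) stop("csv record lacks '# fs:' header: ", path)
  long <- utils::read.csv(path, comment.char = "#")
  leads <- split(long$amplitude_mV, long$lead)
  ord <- order(long$sample[long$lead == names(leads)[1]])
  sig <- do.call(cbind, lapply(leads, function(v) v[ord]))
  a <- utils::read.csv(csv_annotation_path(path))
  beats <- data.frame(p_on = round(a$p_on * fs / 1000), q_on = round(a$q_on * fs / 1000),
                      j_point = round(a$j_point * fs / 1000), t_end = round(a$t_end * fs / 1000))
  annotated_ecg(sig, fs, beats, meta)
}
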