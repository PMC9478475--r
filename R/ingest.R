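#' Load annotated word productions from WAV recordings
#'
#' Real-audio ingestion path: a CSV annotation table gives, per production,
#' the talker, word, pair, repetition, the WAV file and the word's start/end
#' times within it. Each segment is cut out and formant-tracked, yielding
#' `vowel_token`s ready for [featurize()].
#'
#' @param annotations path to a CSV with columns `talker_id`, `word_id`,
#'   `pair_id`, `repetition`, `file`, `start`, `end` (times in seconds).
#' @param audio_dir directory holding the WAV files.
#' @param ceiling,frame_step passed to [measure_formants()].
#' @return list of `vowel_token`s with measured `f1_track`/`f2_track`.
#' @export
tokens_from_annotations <- function(annotations, audio_dir = ".",
                                    ceiling = 5500, frame_step = 0.002) {
  ann <- read.csv(annotations, stringsAsFactors = FALSE)
  req <- c("talker_id", "word_id", "pair_id", "repetition", "file", "start", "end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(ann$end <= ann$start)) stop("annotation end times must exceed start times")
  lapply(seq_len(nrow(ann)), function(i) {
    wav <- read_wav(file.path(audio_dir, ann$file[i]))
    fs <- attr(wav, "fs")
    i0 <- max(1L, round(ann$start[i] * fs) + 1L)
    i1 <- min(length(wav), round(ann$end[i] * fs))
    seg <- as.numeric(wav[i0:i1])
    trk <- measure_formants(seg, fs = fs, ceiling = ceiling,
                            frame_step = frame_step)
    structure(list(talker_id = ann$talker_id[i], word_id = ann$word_id[i],
                   pair_id = ann$pair_id[i],
                   repetition = as.integer(ann$repetition[i]),
                   times = trk$time, f1_track = trk$f1, f2_track = trk$f2,
                   f0_track = NULL, duration = (i1 - i0 + 1L) / fs,
                   audio = seg, fs = fs),
              class = "vowel_token")
  })
}
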