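# Minimal Standard MIDI File support: enough to round-trip monophonic
# note streams (type 0/1, metrical division, tempo map).  Velocities and
# all controller data are ignored on read.

smf_varint_read <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- bytes[pos]; pos <- pos + 1L
    val <- val * 128 + (b %% 128)
    if (b < 128) break
  }
  list(value = val, pos = pos)
}

smf_varint_encode <- function(x) {
  out <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    out <- c(as.raw(128 + x %% 128), out)
    x <- x %/% 128
  }
  out
}

smf_u <- function(bytes, pos, n) {
  v <- 0
  for (i in seq_len(n)) v <- v * 256 + bytes[pos + i - 1L]
  v
}

# Read a Standard MIDI File; returns data.frame(onset, duration, note) in ms.
smf_read <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  bytes <- as.integer(raw)
  if (length(bytes) < 14 || rawToChar(raw[1:4]) != "MThd") {
    stop("not a Standard MIDI File (missing MThd): ", path, call. = FALSE)
  }
  ntrks <- smf_u(bytes, 11, 2)
  division <- smf_u(bytes, 13, 2)
  if (division >= 32768) {
    stop("SMPTE time division not supported: ", path, call. = FALSE)
  }
  pos <- 15L
  tempo_changes <- list(list(tick = 0, tempo = 500000))
  notes_on <- list()
  notes <- list()
  for (trk in seq_len(ntrks)) {
    if (pos + 7 > length(bytes) || rawToChar(raw[pos:(pos + 3)]) != "MTrk") {
      stop(sprintf("malformed MIDI: expected MTrk for track %d at byte %d", trk, pos),
           call. = FALSE)
    }
    len <- smf_u(bytes, pos + 4L, 4)
    p <- pos + 8L
    end <- p + len
    tick <- 0
    status <- NA_integer_
    while (p < end) {
      vr <- smf_varint_read(bytes, p); p <- vr$pos
      tick <- tick + vr$value
      b <- bytes[p]
      if (b >= 128) { status <- b; p <- p + 1L }
      if (is.na(status)) stop("malformed MIDI: data byte without status at byte ", p,
                              call. = FALSE)
      if (status == 255) {            # meta
        type <- bytes[p]; p <- p + 1L
        vr <- smf_varint_read(bytes, p); p <- vr$pos
        if (type == 81 && vr$value == 3) {
          tempo_changes[[length(tempo_changes) + 1L]] <-
            list(tick = tick, tempo = smf_u(bytes, p, 3))
        }
        p <- p + vr$value
        status <- NA_integer_
      } else if (status %in% c(240, 247)) {  # sysex
        vr <- smf_varint_read(bytes, p); p <- vr$pos
        p <- p + vr$value
        status <- NA_integer_
      } else {
        kind <- status %/% 16
        nd <- if (kind %in% c(12, 13)) 1L else 2L
        d1 <- bytes[p]
        d2 <- if (nd == 2L) bytes[p + 1L] else NA_integer_
        p <- p + nd
        if (kind == 9 && d2 > 0) {          # note on
          key <- as.character(d1)
          if (!is.null(notes_on[[key]])) {
            stop("overlapping MIDI notes: note ", d1, " re-struck at tick ", tick,
                 call. = FALSE)
          }
          notes_on[[key]] <- tick
        } else if (kind == 8 || (kind == 9 && d2 == 0)) {  # note off
          key <- as.character(d1)
          if (!is.null(notes_on[[key]])) {
            notes[[length(notes) + 1L]] <-
              list(note = d1, on = notes_on[[key]], off = tick)
            notes_on[[key]] <- NULL
          }
        }
      }
    }
    pos <- end
  }
  if (!length(notes)) {
    return(data.frame(onset = numeric(0), duration = numeric(0), note = integer(0)))
  }
  # tick -> ms through the tempo map
  tc <- do.call(rbind, lapply(tempo_changes, as.data.frame))
  tc <- tc[!duplicated(tc$tick, fromLast = TRUE), , drop = FALSE]
  tc <- tc[order(tc$tick), , drop = FALSE]
  ms_at <- cumsum(c(0, diff(tc$tick) * tc$tempo[-nrow(tc)] / (division * 1000)))
  tick_to_ms <- function(t) {
    i <- findInterval(t, tc$tick)
    ms_at[i] + (t - tc$tick[i]) * tc$tempo[i] / (division * 1000)
  }
  on <- vapply(notes, function(x) x$on, 0)
  off <- vapply(notes, function(x) x$off, 0)
  nt <- vapply(notes, function(x) x$note, 0L)
  o <- order(on)
  data.frame(onset = tick_to_ms(on[o]),
             duration = tick_to_ms(off[o]) - tick_to_ms(on[o]),
             note = nt[o])
}

# Write a monophonic type-0 SMF at 120 bpm, division 480 (1 tick = 1/960 s
# = 500/480 ms); integer-ms onsets are represented exactly when divisible
# by 25/24 ms -- callers needing exact timing should keep to the CSV format.
smf_write <- function(notes, path, division = 480L, tempo = 500000L) {
  ms_to_tick <- function(ms) as.integer(round(ms * division * 1000 / tempo))
  evs <- data.frame(
    tick = c(ms_to_tick(notes$onset), ms_to_tick(notes$onset + notes$duration)),
    note = c(notes$note, notes$note),
    on = rep(c(TRUE, FALSE), each = nrow(notes)))
  evs <- evs[order(evs$tick, evs$on), , drop = FALSE]  # offs before ons at same tick
  body <- c(smf_varint_encode(0), as.raw(c(255, 81, 3)),
            as.raw(c(tempo %/% 65536, (tempo %/% 256) %% 256, tempo %% 256)))
  last <- 0L
  for (i in seq_len(nrow(evs))) {
    body <- c(body, smf_varint_encode(evs$tick[i] - last),
              as.raw(c(if (evs$on[i]) 144 else 128, evs$note[i],
                       if (evs$on[i]) 64 else 0)))
    last <- evs$tick[i]
  }
  body <- c(body, smf_varint_encode(0), as.raw(c(255, 47, 0)))
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("MThd"), u32(6), u16(0), u16(1), u16(division),
             charToRaw("MTrk"), u32(length(body)), body), con)
  invisible(path)
}
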