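# shared study-condition fixtures: the frozen synthetic locus plus donors
fix_switch3 <- example_locus("switch3")
fix_ins12 <- example_locus("ins12")

# is every indel event leftmost-equivalent? (the standard left-alignment
# normalisation: an indel preceded by a match column cannot be shifted left
# without changing score or validity)
indels_left_normalized <- function(ref, events) {
  rch <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    if (!ev$kind %in% c("insertion", "deletion")) next
    if (ev$ref_pos == 0L) next
    # the column immediately before the indel must be a match for a shift to
    # be possible at all; events are maximal runs, so it is unless the
    # previous event is a mismatch/indel ending exactly there
    prev <- events[events$ref_pos < ev$ref_pos |
                   (events$kind == "insertion" & events$ref_pos == ev$ref_pos), ,
                   drop = FALSE]
    prev_kinds <- prev$kind[prev$ref_pos + ifelse(prev$kind == "insertion",
                                                  0L, prev$length) == ev$ref_pos]
    if (any(prev_kinds %in% c("mismatch", "insertion", "deletion"))) next
    if (ev$kind == "deletion") {
      # shifting left needs ref[pos-1] == ref[pos+len-1]
      if (rch[ev$ref_pos] == rch[ev$ref_pos + ev$length]) return(FALSE)
    } else {
      last_ins <- substr(ev$bases, ev$length, ev$length)
      if (rch[ev$ref_pos] == last_ins) return(FALSE)
    }
  }
  TRUE
}
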