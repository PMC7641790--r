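# Small builders used across tests; everything is constructed in code.

# chain: root -> s1 -> ... -> s{n_screens} -> one target element
chain_tree <- function(n_screens) {
  leaf <- list(label = "element", kind = "data_element", is_target = TRUE)
  spine <- leaf
  for (d in rev(seq_len(n_screens))) {
    spine <- list(label = paste0("S", d), kind = "screen",
                  children = list(spine))
  }
  nav_tree_from_list(list(label = "root", kind = "screen",
                          children = list(spine)))
}

# session from label/start/end triplets
mk_session <- function(labels, starts, ends, id = "s1", screen_id = NULL) {
  seg <- data.frame(task = labels, start_s = starts, end_s = ends,
                    stringsAsFactors = FALSE)
  if (!is.null(screen_id)) seg$screen_id <- screen_id
  session(id, seg)
}

# contiguous unit-step session from a label sequence
mk_seq_session <- function(labels, step = 10, id = "s1", screen_id = NULL) {
  n <- length(labels)
  mk_session(labels, (seq_len(n) - 1) * step, seq_len(n) * step, id = id,
             screen_id = screen_id)
}
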