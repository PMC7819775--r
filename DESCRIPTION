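Package: chatmatch
Title: Content-Based Retrieval of Similar Helpline Chat Segments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supports chat counselors by retrieving past conversation
    segments similar to an ongoing chat. Transcripts are cleaned, filtered
    to a minimum number of messages, and segmented into overlapping
    five-message windows; each window is embedded by smooth-inverse-frequency
    (SIF) weighted averaging of pretrained word vectors, and the ten most
    cosine-similar windows to the tail of the ongoing conversation are
    recommended. Includes a seeded generator of topic-structured synthetic
    chat corpora with ground truth, and an in-silico matched-versus-random
    validity experiment with precision-at-k reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
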