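# Annotation ingestion defaults: tier names, label-to-category table, and the
# minimum-silence threshold (seconds). Labels not listed here fall back to the
# number lexicon; an explicit "label#category" marker in the TextGrid always
# wins.
tiers:
  words: "words"
  phones: "phones"
labels:
  filled_pause: ["euh", "um", "hum", "eh", "mm"]
  abnormal_breathing: ["[breath]", "[inspiration]"]
  vocal_noise: ["[noise]", "[click]", "[cough]", "[laugh]"]
silence:
  min_silence: 0.1
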