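# Traditional (binary) scoring of four-category questionnaire responses:
# 1-2-3-4 recoded to 0-0-1-1. Applies to every item.
all:
  '1': 0
  '2': 0
  '3': 1
  '4': 1
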