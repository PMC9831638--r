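P2
# range -71.162762711250295 60.529516190198308
16 16
65535
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 50733 47485 55332 55901 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 35166 42037 33818 47880 49181 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 54390 53261 24701 0 10839 30019 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 58461 51001 33065 26079 27873 57811 56887 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 30510 52134 30645 48903 65535 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 60057 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 62388 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422 34422
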