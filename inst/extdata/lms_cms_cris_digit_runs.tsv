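# Transcription of the published LMS x CMS / LMS x CRIS correspondence
# table for resected colorectal cancer liver metastases. Text extraction
# collapsed each row's nine counts (CMS1-4 then CRIS-A..E) into a single
# digit run; parse with lmsubtype::lms_concordance_counts().
row	digit_run
LMS1	104171312103
LMS2	080141612
LMS3	015010334105
LMS4	03202433125
LMS5	1003893482
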