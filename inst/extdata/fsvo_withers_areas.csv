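category,area_m2
<120,4.0
120-134,4.5
134-148,5.5
148-162,6.0
162-175,7.5
>175,8.0
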