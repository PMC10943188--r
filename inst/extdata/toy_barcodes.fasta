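>s1
ATGGCTCATGCA
>s2
ATGGCTCATGCT
>s3
ATGGCTCNTGCA
>s4
CGATTACATGCA
>s5
CGATTACATGCT
>s6
CGATTACCTGCA
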