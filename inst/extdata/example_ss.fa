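>SYN0001
CCCCHHHHHEECCCCCCCCCCCCHECCCCEEECEEEEEEEEEEEEHHHHHHHHHHHEEEEEEHHHHHCCCCCCCCCCCCCCCCCCCHEEEHHHHHHHHEEHHHHEEEEEHHCCCCCCCCCCCCCCCHH
>SYN0002
EEEEEEEEEEEEEEEEEEEEEEEEEEECCCCCCCCEEEEHHHHHHHHHHHHHCCCCCCCCCCHHHHHCCCCCCCCCCCCCCCHHCCCCCCCEECEHEEEEEEEEEEEEEEEEECHH
>SYN0003
CCCCCCCCCCCCCCCCCHHHHHEECHEHHHHHEEEEEEEEEEEEECCCEEEEEEEEEEEEEEEEEEEECCCCCCCCEEEE
>SYN0004
HHHHHHHHEEECCEEEEEEEEEEEEEEEEEECCCCCCHHEEECHHHHHEHHEHHHHHCCCCEEEEEECEEEEEEEEEEEEEHHHHHHHHCEHCCCCEHEHHHHH
>SYN0005
CCCEEEEEEEEEEEEHHEHHEEEEEEEECCCCCCHHHHHEHHHHEEEEEEHHHHHHHHHHHHHHHCHHHHHHHHCCCCEEEEEEECCCC
>SYN0006
HHHHHHHCEHEEEEEEEEEEEEHCCCCCCCCCCEEEEEEHHHHHHHHHHHEEECCCCCHHHHHHHHHCCCEECCEEEEEEEEEEEEEEEHHHHHHHHHHHHHEEEEEECCCHHHC
>SYN0007
EEEHHHHHEEEECCCCCCCCCCCCCCEEEEEEEEECCCCCCCCCCCCCCCHHHCCCEEEHHHECCHHHHEEEEHHHHHHHCCCEEECHHHHEEEEEE
>SYN0008
HHHCCCCHHHHHHHECCCCCCCCCCCCCCCCEEEECCHHEEEEEEEEEEEHHHHHHHHEEEEEEEEEEEEHCCCCCEEEECCEEEECHHHHHHCEECCCCCCCCCEEEEHHHHHHHHHHHEHCCEEEEEEEECCCCC
>SYN0009
CCCEECCCCCCCHHHHCCCCCCHHHHHHHHCCCCCCCCCCCCCCCCCCHHHEEEEEEEEEEEEEEEEEEEEHHHCCCCCCCCHHHHHEHHHHHHHHHHEEEHHEEEEEEECCCCCCCCCHHEEEEHHH
>SYN0010
EEEEEEEEEHHHHHHHHCCCCCCCEEEEHHEEEEEEEHHHHEHHCHHCCEHHHHHHHHHHCHHHHHHEEEHHCCCEEEEEEEEEEEEECCCCHHHCCCCCEEEEEEEEECCCCCCCHHHHHHHHHH
>SYN0011
HHHHHHCCCCCEEEEEEHHHHECCCCCEEEHHHHHHHECCCCCCCHHHHHHHHCCHHHHHHHHHCCCCCHHHHHHHHHHHHHEEEEEHHHHHHCEEEEEEHHH
>SYN0012
CCCCCCECCEEEEHHHHHEEECCCCCCCHHCCCCCCCCCCCCCCCCCEEEEEEEEEEEECCHHHHHHHHHEHHHHHHHHHHHHHHC
>SYN0013
EEEHHCCCCCHHHHHHHHHHHHHCECCEEHHHHCCCCCCCCHHHHEEHHEECCCCHHHHECCCEEEEEEEEECCHCCCEEEEEEEEECCCECHHHHHHCCCCCEHHHHEEECCCC
>SYN0014
HHHHHHHHHHCCCEEECCCEEEEEEEEEEEHHHHHHHEEEEEEEEEEEEEEHHHHHHHHHHHHHHHHEEEEEEEEEHHHHHHHHHHHHHHHCCEECCCCHHHHH
>SYN0015
HHHHHHCCCCCCEEEEEEEEEEEHHHHHHHEEHHHHHHHHHHEEEEEEEEECHCCCCHHEEEEHHHHHHHEEEEEEHHEEEECCEEECCCCCCCCCCCCCCCEEEEEHHCEEEEEE
>SYN0016
CECCCCCCCEEEEEEHCCEEEHEEEEEEEEHHEEEEEEEEEEEEEEEEEEEEEEEEEHEEEEEEEHHHHHHHHHHHHHCCCHHHHCCCCCCCCCCCHHHHHHHHCCCHHHHCCCCHHHHHHHHHE
>SYN0017
CCEEEEEHHHHHHHCHHHHHCCCCCHHCHHHHCCCCCCCCEEEEHHCCCEECCCHHHHHHHHEHHHHHHEEEEEEEHHHHHHEEEEEHHHHHCCHHHHH
>SYN0018
HHHHHHHHHHHHHHHHHCHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHEEEEEEEEEEEHHCCCCECHHCEEEEEEEEECCCCCCCCCCCHHEEEEEHHHH
>SYN0019
CCCCCCCECCCCCCCCCCCCCCECCCCCCHCCCCHCCHHHHHHHHHHHHHHEEEEEEEEEEEEEEECCCCCCCCCEECCCCCCCCCCCCCCCECCCHHHHECHHHHHHHCCCEEECCCCCEEEEEEHHH
>SYN0020
CCEEHHHHHHHHHCHHCCCCECHHEECCCCCHHHECCCHHHHHHHHHHEEEECCCCCCCCCCCEEEEHHHHHHHHHHHHHHHCEEEEEEEEEHHCEECCCCCCHHHCCCCCCCEEEEEEEEEEEEE
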