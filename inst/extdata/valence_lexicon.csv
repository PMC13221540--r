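word,valence
love,3.2
loved,2.9
loves,2.7
amazing,2.8
awesome,3.1
wonderful,2.7
excellent,3.2
excited,2.2
exciting,2.3
excitement,2.0
happy,2.7
happiness,2.6
thrilled,2.8
delighted,2.9
delightful,2.8
fascinating,2.1
interesting,1.7
incredible,2.5
cool,1.3
great,3.1
good,1.9
nice,1.8
glad,2.0
enjoy,1.9
enjoyed,2.0
enjoyable,2.1
fun,2.3
beautiful,2.9
best,3.2
better,1.9
helpful,1.8
thanks,1.9
thank,1.9
grateful,2.2
pleased,2.0
pleasant,2.3
perfect,2.7
impressive,2.2
impressed,2.1
satisfying,2.0
satisfied,1.9
proud,2.1
wow,2.8
brilliant,2.8
lovely,2.6
recommend,1.6
recommended,1.5
positive,1.8
worth,1.2
easy,1.1
clear,1.0
accurate,1.1
correct,1.2
confirmed,0.9
fine,0.8
wild,0.5
unbelievable,0.4
surprised,0.9
surprising,0.7
curious,0.9
hopeful,1.6
relieved,1.6
welcome,1.4
fair,1.1
smooth,1.2
wrong,-2.1
incorrect,-1.8
inaccurate,-1.8
mistake,-1.6
mistakes,-1.6
error,-1.6
errors,-1.7
fake,-1.9
scam,-2.6
doubt,-1.2
doubts,-1.2
skeptical,-1.2
impossible,-1.6
disappointed,-2.2
disappointing,-2.1
disappointment,-2.1
boring,-1.4
letdown,-1.8
terrible,-3.0
awful,-2.9
bad,-2.5
horrible,-2.9
sad,-2.1
unhappy,-2.2
angry,-2.5
mad,-2.2
upset,-1.9
upsetting,-2.0
annoying,-1.9
annoyed,-1.8
frustrating,-2.0
frustrated,-2.0
hate,-2.7
hated,-2.6
worst,-3.1
useless,-1.9
confusing,-1.3
confused,-1.3
worried,-1.7
worry,-1.7
worries,-1.6
crying,-2.1
cried,-1.9
lied,-2.3
lies,-2.0
crisis,-1.7
existential,-0.7
shocked,-0.6
shocking,-0.8
crazy,-0.6
insane,-0.9
broken,-1.9
slow,-1.0
waste,-2.0
wasted,-2.0
problem,-1.4
problems,-1.5
issue,-0.9
issues,-1.0
failed,-2.1
fail,-1.9
failure,-2.2
poor,-1.9
cheap,-0.8
misleading,-1.9
lost,-1.3
hurt,-1.9
hurts,-1.8
painful,-2.2
stress,-1.6
stressful,-1.8
scared,-1.9
afraid,-1.8
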