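{"tweet_id":"t1","user_id":"A","day":1,"is_retweet":false,"root_tweet_id":"t1","urls":[],"hashtags":[]}
{"tweet_id":"r1","user_id":"B","day":1,"is_retweet":true,"root_tweet_id":"t1","urls":[],"hashtags":[]}
{"tweet_id":"r2","user_id":"C","day":1,"is_retweet":true,"root_tweet_id":"t1","urls":[],"hashtags":[]}
{"tweet_id":"r3","user_id":"D","day":1,"is_retweet":true,"root_tweet_id":"t1","urls":[],"hashtags":[]}
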